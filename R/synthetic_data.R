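#' Configuration for the synthetic bacterial genome generator
#'
#' The generator emulates the inputs of a genome-wide stop-codon landscape
#' study: protein-coding genes drawn from a codon-usage model, AT-rich
#' intergenic spacers, configurable strand layout and operon grouping, and
#' optionally planted GC hairpins of known stability immediately downstream
#' of stop codons, with a ground-truth table for recovery benchmarks.
#'
#' @param n_genes number of genes (default 200).
#' @param gene_len_range CDS length range in codons, start and stop
#'   included (default 50-300).
#' @param codon_usage named per-codon weights (e.g.
#'   [codon_usage_ecoli()]); `NULL` = uniform within each synonymous
#'   family.
#' @param intergenic_gc GC fraction of intergenic sequence (default 0.25;
#'   bacterial intergenic regions are AT-rich, which also keeps baseline
#'   downstream structure weak).
#' @param intergenic_range intergenic distance range in nt (default
#'   40-150, so all genes are topology-eligible under the 25-nt rule).
#' @param frac_opposite_strand fraction of genes placed on the minus
#'   strand (default 0).
#' @param operon_size_probs probabilities for operon sizes 1, 2, ...
#'   (default `c(.4, .3, .2, .1)`).
#' @param hairpin `NULL`, or a list with `fraction` (of genes), `stem_len`
#'   (G-C pairs, >= 3), `loop` (default `"GAAA"`), `offset` (opening
#'   position of the hairpin's 5' end downstream of the stop, default +5).
#' @param stop_codon_probs named probabilities for TAA/TAG/TGA.
#' @param pad terminal padding (nt) at both contig ends (default 150, so
#'   all landscape windows exist).
#' @param contig_id contig name.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_genes = 200L, gene_len_range = c(50L, 300L),
                         codon_usage = NULL, intergenic_gc = 0.25,
                         intergenic_range = c(40L, 150L),
                         frac_opposite_strand = 0,
                         operon_size_probs = c(.4, .3, .2, .1),
                         hairpin = NULL,
                         stop_codon_probs = c(TAA = 1/3, TAG = 1/3, TGA = 1/3),
                         pad = 150L, contig_id = "synth_1") {
  if (!is.null(hairpin)) {
    hairpin <- modifyList(list(fraction = 0, stem_len = 12L, loop = "GAAA",
                               offset = 5L), hairpin)
    stopifnot(hairpin$fraction >= 0, hairpin$fraction <= 1,
              hairpin$stem_len >= 3L)
  }
  stopifnot(frac_opposite_strand >= 0, frac_opposite_strand <= 1,
            intergenic_gc >= 0, intergenic_gc <= 1,
            gene_len_range[1] >= 14L)   # >= 42 nt, clears the 40-nt QC floor
  structure(list(n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range),
                 codon_usage = codon_usage, intergenic_gc = intergenic_gc,
                 intergenic_range = as.integer(intergenic_range),
                 frac_opposite_strand = frac_opposite_strand,
                 operon_size_probs = operon_size_probs,
                 hairpin = hairpin, stop_codon_probs = stop_codon_probs,
                 pad = as.integer(pad), contig_id = contig_id),
            class = "synth_config")
}

#' Approximate E. coli K-12 codon usage (relative frequencies per 1000)
#'
#' An optional preset for [synth_config()]'s codon-usage model; values are
#' approximate and serve only to bias synonymous-codon draws realistically.
#' @return named numeric vector over the 61 sense codons.
#' @export
codon_usage_ecoli <- function() {
  c(TTT = 22.2, TTC = 16.6, TTA = 13.9, TTG = 13.7, CTT = 11.0, CTC = 11.0,
    CTA = 3.9, CTG = 52.6, ATT = 30.3, ATC = 25.1, ATA = 4.4, ATG = 27.9,
    GTT = 18.3, GTC = 15.3, GTA = 10.9, GTG = 26.4, TCT = 8.5, TCC = 8.6,
    TCA = 7.2, TCG = 8.9, CCT = 7.0, CCC = 5.5, CCA = 8.4, CCG = 23.2,
    ACT = 9.0, ACC = 23.4, ACA = 7.1, ACG = 14.4, GCT = 15.3, GCC = 25.5,
    GCA = 20.1, GCG = 33.6, TAT = 16.2, TAC = 12.2, CAT = 12.9, CAC = 9.7,
    CAA = 15.3, CAG = 28.8, AAT = 17.7, AAC = 21.7, AAA = 33.6, AAG = 10.3,
    GAT = 32.1, GAC = 19.1, GAA = 39.4, GAG = 17.8, TGT = 5.2, TGC = 6.4,
    TGG = 15.2, CGT = 20.9, CGC = 22.0, CGA = 3.6, CGG = 5.4, AGT = 8.8,
    AGC = 16.1, AGA = 2.1, AGG = 1.2, GGT = 24.7, GGC = 29.6, GGA = 8.0,
    GGG = 11.1)
}

#' Design a GC-stem hairpin with a known strong fold
#'
#' `stem_len` G residues, the loop, then `stem_len` C residues; the two
#' arms are exact reverse complements, so the minimum-free-energy structure
#' is the intended stem-loop and its stability grows with `stem_len`.
#'
#' @param stem_len number of G-C pairs (>= 3).
#' @param loop loop sequence (default `"GAAA"`, a stable tetraloop).
#' @return character scalar of length `2 * stem_len + nchar(loop)`.
#' @export
design_hairpin <- function(stem_len, loop = "GAAA") {
  stopifnot(stem_len >= 3L, nchar(loop) >= 3L)
  paste0(strrep("G", stem_len), toupper(loop), strrep("C", stem_len))
}

sense_codon_pool <- function(translation_table = 11L) {
  gc <- Biostrings::getGeneticCode(as.character(translation_table))
  names(gc)[gc != "*"]
}

random_intergenic <- function(len, gc) {
  if (len == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic genome with ground truth
#'
#' Lays genes out on one contig as alternating CDS and intergenic spacer,
#' samples codons from the configured usage model (uniform within
#' synonymous families by default), terminates each CDS with a stop codon,
#' optionally plants hairpins whose 5' end opens at a fixed position
#' downstream of the stop (overwriting intergenic sequence, so distances
#' stay as configured), flips a configurable fraction of genes to the
#' minus strand, and groups consecutive same-strand genes into operons.
#' Byte-reproducible from the seed.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param dir optional output directory; when given, writes
#'   `genome.fasta`, `genes.gff3`, `operons.tsv` and `truth.tsv`.
#' @param engine optional [fold_engine] used to record each planted
#'   hairpin's folded energy in the truth table.
#' @return list `genome` (`DNAStringSet`), `genes` (gene table as from
#'   [parse_genome()]), `operons`, `truth`, and `paths` when `dir` was
#'   given. The truth table has one row per gene: `gene_id`,
#'   `hairpin_planted`, `stem_len`, `target_offset`, `hairpin_dg`,
#'   `intergenic_distance`, `same_strand`, `operon_position`.
#' @export
make_genome <- function(config, seed = 1L, dir = NULL, engine = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(seed, 0L))
  n <- config$n_genes
  pool <- sense_codon_pool()
  usage <- config$codon_usage
  w <- if (is.null(usage)) setNames(rep(1, length(pool)), pool) else usage[pool]
  w[is.na(w)] <- 0
  stopifnot(sum(w) > 0)

  hp <- config$hairpin
  planted <- rep(FALSE, n)
  if (!is.null(hp) && hp$fraction > 0) {
    planted[sample.int(n, round(hp$fraction * n))] <- TRUE
  }
  hp_seq <- if (!is.null(hp)) design_hairpin(hp$stem_len, hp$loop) else NULL

  strands <- ifelse(runif(n) < config$frac_opposite_strand, "-", "+")
  lens <- sample(seq.int(config$gene_len_range[1], config$gene_len_range[2]),
                 n, replace = TRUE)
  gaps <- sample(seq.int(config$intergenic_range[1], config$intergenic_range[2]),
                 n, replace = TRUE)

  units <- character(n)
  cds_off <- integer(n)   # CDS offset within unit (0-based), forward strand
  cds_len <- integer(n)
  for (i in seq_len(n)) {
    n_cod <- lens[i]
    body <- sample(pool, n_cod - 2L, replace = TRUE, prob = w)
    stopc <- sample(names(config$stop_codon_probs), 1L,
                    prob = config$stop_codon_probs)
    cds <- paste(c("ATG", body, stopc), collapse = "")
    gap <- random_intergenic(gaps[i], config$intergenic_gc)
    if (planted[i]) {
      if (hp$offset + nchar(hp_seq) > gaps[i]) {
        stop("hairpin (offset ", hp$offset, " + ", nchar(hp_seq),
             " nt) does not fit the ", gaps[i],
             "-nt intergenic region of gene g", i)
      }
      substr(gap, hp$offset + 1L, hp$offset + nchar(hp_seq)) <- hp_seq
    }
    unit <- paste0(cds, gap)
    cds_len[i] <- nchar(cds)
    if (strands[i] == "-") {
      unit <- revcomp(unit)
      cds_off[i] <- gaps[i]
    } else {
      cds_off[i] <- 0L
    }
    units[i] <- unit
  }
  lead <- random_intergenic(config$pad, config$intergenic_gc)
  trail <- random_intergenic(config$pad, config$intergenic_gc)
  contig <- paste0(lead, paste(units, collapse = ""), trail)

  unit_starts <- config$pad + c(0L, cumsum(nchar(units))[-n])  # 0-based
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    contig_id = config$contig_id, strand = strands,
    cds_start = unit_starts + cds_off,
    cds_end = unit_starts + cds_off + cds_len,
    multi_part = FALSE, translation_table = 11L,
    stringsAsFactors = FALSE
  )
  genome <- Biostrings::DNAStringSet(setNames(contig, config$contig_id))

  # operons: consecutive same-strand genes, sizes from the configured law
  sizes <- config$operon_size_probs
  op_id <- integer(n); pos_idx <- integer(n)
  i <- 1L; op <- 0L
  while (i <= n) {
    op <- op + 1L
    k <- sample.int(length(sizes), 1L, prob = sizes)
    j <- i
    while (j < min(i + k - 1L, n) && strands[j + 1L] == strands[i]) j <- j + 1L
    members <- i:j
    if (strands[i] == "-") members <- rev(members)  # transcription order
    op_id[members] <- op
    pos_idx[members] <- seq_along(members)
    i <- j + 1L
  }
  operons <- data.frame(operon_id = sprintf("op%03d", op_id),
                        gene_id = genes$gene_id,
                        position_index = pos_idx, stringsAsFactors = FALSE)

  topo <- pair_topology(genes)
  hp_dg <- NA_real_
  if (!is.null(engine) && !is.null(hp_seq)) hp_dg <- mfe(engine, hp_seq)
  truth <- data.frame(
    gene_id = genes$gene_id,
    hairpin_planted = planted,
    stem_len = if (!is.null(hp)) ifelse(planted, hp$stem_len, NA) else NA,
    target_offset = if (!is.null(hp)) ifelse(planted, hp$offset, NA) else NA,
    hairpin_dg = ifelse(planted, hp_dg, NA),
    intergenic_distance = topo$intergenic_distance[match(genes$gene_id, topo$gene_id)],
    same_strand = topo$same_strand[match(genes$gene_id, topo$gene_id)],
    operon_position = unname(operon_positions(operons, genes)[genes$gene_id]),
    stringsAsFactors = FALSE
  )

  out <- list(genome = genome, genes = genes, operons = operons, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "genome.fasta"),
                  gff = file.path(dir, "genes.gff3"),
                  operons = file.path(dir, "operons.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    Biostrings::writeXStringSet(genome, paths$fasta)
    write_gff3(genes, paths$gff)
    write.table(operons, paths$operons, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Write a gene table as GFF3 (CDS features, 1-based inclusive)
#' @param genes gene table (0-based half-open coordinates).
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\trtscan\tCDS\t%d\t%d\t.\t%s\t0\tID=cds_%s;gene_id=%s",
                     genes$contig_id, genes$cds_start + 1L, genes$cds_end,
                     genes$strand, genes$gene_id, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic reporter-library read table with per-read truth
#'
#' Uniform random 24-nt variable regions with geometric-ish counts,
#' assigned to bins either by folded clone-window energy octiles (when an
#' engine is given, emulating an expression sort) or round-robin.
#'
#' @param n_reads number of unique reads.
#' @param n_bins number of bins (default 8).
#' @param seed RNG seed.
#' @param engine optional [fold_engine] for energy-based binning.
#' @return list `reads` (`bin_id`, `variable_seq`, `count`) and `truth`
#'   (`variable_seq`, `has_inframe_start`, `has_inframe_stop`, `dg`).
#' @export
make_library_reads <- function(n_reads, n_bins = 8L, seed = 1L, engine = NULL) {
  set.seed(derive_seed(seed, 0L))
  seqs <- unique(random_seqs(n_reads * 2L, 24L))[seq_len(n_reads)]
  counts <- 1L + rpois(n_reads, 2)
  dg <- rep(NA_real_, n_reads)
  if (!is.null(engine)) {
    dg <- variable_region_dg(engine, seqs)
    br <- quantile(dg, probs = seq(0, 1, length.out = n_bins + 1L))
    br[1] <- -Inf; br[length(br)] <- Inf
    bin <- cut(dg, breaks = unique(br), labels = FALSE, include.lowest = TRUE)
  } else {
    bin <- rep_len(seq_len(n_bins), n_reads)
  }
  truth <- data.frame(
    variable_seq = seqs,
    has_inframe_start = vapply(seqs, function(s) any(in_frame_codons(s) %in% START_CODONS),
                               logical(1), USE.NAMES = FALSE),
    has_inframe_stop = vapply(seqs, function(s) any(in_frame_codons(s) %in% STOP_CODONS),
                              logical(1), USE.NAMES = FALSE),
    dg = dg, stringsAsFactors = FALSE
  )
  list(reads = data.frame(bin_id = sprintf("P%d", bin), variable_seq = seqs,
                          count = counts, stringsAsFactors = FALSE),
       truth = truth)
}
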