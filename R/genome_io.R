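#' Parse a genome FASTA and GFF3 annotation into gene models
#'
#' Reads a (multi-)FASTA genome and a GFF3 annotation, keeps `CDS` features,
#' groups them per gene and returns 0-based half-open coordinates on the
#' forward strand. GFF3 coordinates are 1-based inclusive at the boundary.
#'
#' @param fasta_path path to the genome FASTA.
#' @param gff_path path to the GFF3 annotation (CDS features; gene identity
#'   taken from the `gene_id`, `Parent` or `ID` attribute, in that order).
#' @param translation_table NCBI genetic code identifier applied to all
#'   genes (bacterial annotations rarely carry one per gene). Default 11.
#' @return a list with `genome` (a [Biostrings::DNAStringSet], uppercase)
#'   and `genes`, a data.frame with columns `gene_id`, `contig_id`,
#'   `strand`, `cds_start`, `cds_end` (0-based half-open), `multi_part`,
#'   `translation_table`, sorted by contig then start.
#' @export
parse_genome <- function(fasta_path, gff_path, translation_table = 11L) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  if (!file.exists(gff_path)) stop("GFF3 not found: ", gff_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome <- Biostrings::DNAStringSet(toupper(genome))

  gff <- rtracklayer::import(gff_path, format = "gff3")
  gff <- gff[gff$type == "CDS"]
  if (length(gff) == 0L) stop("no CDS features in ", gff_path)

  ids <- rep(NA_character_, length(gff))
  meta <- S4Vectors::mcols(gff)
  pick <- function(col) {
    if (!col %in% names(meta)) return(rep(NA_character_, length(gff)))
    v <- meta[[col]]
    if (is(v, "List") || is.list(v)) {
      v <- vapply(v, function(x) if (length(x)) as.character(x[[1]]) else NA_character_,
                  character(1))
    }
    as.character(v)
  }
  for (col in c("gene_id", "Parent", "ID")) {
    cand <- pick(col)
    ids <- ifelse(is.na(ids) & !is.na(cand) & nzchar(cand), cand, ids)
  }
  if (anyNA(ids)) stop("CDS features without gene_id/Parent/ID attribute")

  contig <- as.character(GenomicRanges::seqnames(gff))
  missing_contig <- setdiff(unique(contig), names(genome))
  if (length(missing_contig)) {
    stop("GFF3 references contig(s) absent from FASTA: ",
         paste(missing_contig, collapse = ", "))
  }

  df <- data.frame(
    gene_id = ids, contig_id = contig,
    strand = as.character(GenomicRanges::strand(gff)),
    start1 = GenomicRanges::start(gff), end1 = GenomicRanges::end(gff),
    stringsAsFactors = FALSE
  )
  parts <- split(df, df$gene_id)
  genes <- do.call(rbind, lapply(parts, function(g) {
    if (length(unique(g$contig_id)) > 1L || length(unique(g$strand)) > 1L) {
      stop("gene ", g$gene_id[1], " spans multiple contigs or strands")
    }
    data.frame(
      gene_id = g$gene_id[1], contig_id = g$contig_id[1], strand = g$strand[1],
      cds_start = min(g$start1) - 1L,   # 1-based inclusive -> 0-based half-open
      cds_end = max(g$end1),
      multi_part = nrow(g) > 1L,
      translation_table = as.integer(translation_table),
      stringsAsFactors = FALSE
    )
  }))
  rownames(genes) <- NULL
  clen <- Biostrings::width(genome)[match(genes$contig_id, names(genome))]
  bad <- genes$cds_start < 0L | genes$cds_end > clen
  if (any(bad)) {
    stop("CDS outside contig bounds for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "))
  }
  genes <- genes[order(genes$contig_id, genes$cds_start, genes$gene_id), ]
  rownames(genes) <- NULL
  list(genome = genome, genes = genes)
}

#' mRNA-sense CDS sequence of one gene
#'
#' @param gene a single row of the gene table.
#' @param genome a `DNAStringSet`.
#' @return character scalar; reverse complement of the forward slice for
#'   minus-strand genes.
#' @export
cds_sequence <- function(gene, genome) {
  s <- as.character(Biostrings::subseq(genome[[gene$contig_id]],
                                       gene$cds_start + 1L, gene$cds_end))
  if (gene$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stop_codons_for <- function(translation_table) {
  gc <- Biostrings::getGeneticCode(as.character(translation_table))
  names(gc)[gc == "*"]
}

#' Quality-filter gene models for landscape analysis
#'
#' Retains genes at least `min_len` nucleotides long, with length divisible
#' by 3, no internal in-frame stop codon, and a terminal stop codon under
#' the gene's translation table. Filtering, not failure: excluded genes are
#' returned with a reason.
#'
#' @param genes gene table from [parse_genome()].
#' @param genome `DNAStringSet`.
#' @param min_len minimum CDS length in nucleotides (default 40).
#' @return list with `genes` (retained rows) and `excluded`, a data.frame
#'   of `gene_id` and `reason` in
#'   `{"short","not_multiple_of_3","internal_stop","no_terminal_stop"}`.
#' @export
qc_filter_genes <- function(genes, genome, min_len = 40L) {
  reasons <- character(0); excluded_ids <- character(0)
  keep <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- g$cds_end - g$cds_start
    reason <- NA_character_
    if (len < min_len) {
      reason <- "short"
    } else if (len %% 3L != 0L) {
      reason <- "not_multiple_of_3"
    } else {
      s <- cds_sequence(g, genome)
      stops <- stop_codons_for(g$translation_table)
      cod <- substring(s, seq(1L, len - 2L, 3L), seq(3L, len, 3L))
      n <- length(cod)
      if (!cod[n] %in% stops) {
        reason <- "no_terminal_stop"
      } else if (n > 1L && any(cod[-n] %in% stops)) {
        reason <- "internal_stop"
      }
    }
    if (is.na(reason)) keep[i] <- TRUE else {
      excluded_ids <- c(excluded_ids, g$gene_id); reasons <- c(reasons, reason)
    }
  }
  list(genes = genes[keep, , drop = FALSE],
       excluded = data.frame(gene_id = excluded_ids, reason = reasons,
                             stringsAsFactors = FALSE))
}

# Anchor of the stop-relative position axis in "oriented contig" coordinates.
# For each gene, windows are substrings of the forward contig (+ strand) or
# its reverse complement (- strand); the anchor is the 0-based index, on that
# oriented string, of the first nucleotide after the stop codon.
axis_anchor <- function(gene, contig_len) {
  if (gene$strand == "+") gene$cds_end else contig_len - gene$cds_start
}

oriented_contigs <- function(genome) {
  fwd <- as.character(genome)
  rev <- vapply(fwd, revcomp, character(1))
  names(rev) <- names(fwd)
  list(fwd = fwd, rev = rev)
}

#' Extract an mRNA-sense window relative to a gene's stop codon
#'
#' The window's 5'-most nucleotide sits at position `p` of the stop-relative
#' axis (p = 0 is the first nucleotide after the stop codon; p = -3 opens at
#' the stop itself). Minus-strand genes are read on the reverse complement.
#'
#' @param gene single gene row.
#' @param genome `DNAStringSet`.
#' @param p opening position on the stop-relative axis.
#' @param width window width in nucleotides.
#' @return character scalar, or `NA_character_` when the window extends
#'   beyond the contig (windows are never padded).
#' @export
sense_window <- function(gene, genome, p, width) {
  ori <- oriented_contigs(genome[gene$contig_id])
  str <- if (gene$strand == "+") ori$fwd[[1]] else ori$rev[[1]]
  a <- axis_anchor(gene, nchar(str))
  s0 <- a + p
  if (s0 < 0L || s0 + width > nchar(str)) return(NA_character_)
  substr(str, s0 + 1L, s0 + width)
}

# Matrix of windows (genes x positions), NA where unavailable. `ori` from
# oriented_contigs(); vectorized over positions per gene.
extract_window_matrix <- function(genes, ori, positions, width) {
  out <- matrix(NA_character_, nrow(genes), length(positions),
                dimnames = list(genes$gene_id, positions))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    str <- if (g$strand == "+") ori$fwd[[g$contig_id]] else ori$rev[[g$contig_id]]
    L <- nchar(str)
    s0 <- axis_anchor(g, L) + positions
    ok <- s0 >= 0L & (s0 + width) <= L
    if (any(ok)) out[i, ok] <- substring(str, s0[ok] + 1L, s0[ok] + width)
  }
  out
}

#' Gene-pair topology: downstream neighbour, intergenic distance, strand
#'
#' For each gene the downstream neighbour is the nearest other CDS in the
#' gene's direction of transcription (on either strand of the same contig);
#' genes wholly nested inside the query gene are skipped. The intergenic
#' distance is the number of nucleotides between the end of this CDS
#' (including its stop codon) and the start of the neighbour's CDS, negative
#' when they overlap.
#'
#' @param genes gene table (one contig or many).
#' @return data.frame with `gene_id`, `next_gene_id`, `downstream_exists`,
#'   `intergenic_distance`, `same_strand`.
#' @export
pair_topology <- function(genes) {
  res <- lapply(split(genes, genes$contig_id), function(g) {
    n <- nrow(g)
    nxt <- rep(NA_character_, n); dist <- rep(NA_integer_, n)
    same <- rep(NA, n)
    for (i in seq_len(n)) {
      if (g$strand[i] == "+") {
        cand <- which(g$cds_start > g$cds_start[i] & g$cds_end > g$cds_end[i])
        if (length(cand)) {
          j <- cand[which.min(g$cds_start[cand])]
          nxt[i] <- g$gene_id[j]
          dist[i] <- g$cds_start[j] - g$cds_end[i]
          same[i] <- g$strand[j] == g$strand[i]
        }
      } else {
        cand <- which(g$cds_end < g$cds_end[i] & g$cds_start < g$cds_start[i])
        if (length(cand)) {
          j <- cand[which.max(g$cds_end[cand])]
          nxt[i] <- g$gene_id[j]
          dist[i] <- g$cds_start[i] - g$cds_end[j]
          same[i] <- g$strand[j] == g$strand[i]
        }
      }
    }
    data.frame(gene_id = g$gene_id, next_gene_id = nxt,
               downstream_exists = !is.na(nxt),
               intergenic_distance = dist, same_strand = same,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Label genes by their position within operons
#'
#' @param operons data.frame `operon_id`, `gene_id`, `position_index`
#'   (transcription order within the operon).
#' @param genes gene table; genes absent from `operons` get `"unassigned"`.
#' @return named character vector over `genes$gene_id` with values in
#'   `{"first","internal","last","monocistronic","unassigned"}`.
#' @export
operon_positions <- function(operons, genes) {
  lab <- setNames(rep("unassigned", nrow(genes)), genes$gene_id)
  if (any(duplicated(operons$gene_id))) stop("a gene appears in more than one operon")
  for (op in split(operons, operons$operon_id)) {
    op <- op[order(op$position_index), ]
    ids <- op$gene_id[op$gene_id %in% names(lab)]
    k <- length(ids)
    if (k == 0L) next
    if (k == 1L) { lab[ids] <- "monocistronic"; next }
    lab[ids[1]] <- "first"
    lab[ids[k]] <- "last"
    if (k > 2L) lab[ids[2:(k - 1L)]] <- "internal"
  }
  lab
}

#' Count efficient start codons downstream of a gene's stop codon
#'
#' Counts every occurrence (any reading frame, overlaps allowed) of the
#' given trinucleotides in the `L` mRNA-sense nucleotides immediately after
#' the stop codon.
#'
#' @param gene single gene row.
#' @param genome `DNAStringSet`.
#' @param L downstream length surveyed (default 50).
#' @param codons start codons counted, default `ATG`, `GTG`, `TTG`.
#' @return list `count`, `L_effective`, `truncated`.
#' @export
downstream_start_census <- function(gene, genome, L = 50L,
                                    codons = c("ATG", "GTG", "TTG")) {
  ori <- oriented_contigs(genome[gene$contig_id])
  str <- if (gene$strand == "+") ori$fwd[[1]] else ori$rev[[1]]
  a <- axis_anchor(gene, nchar(str))
  avail <- nchar(str) - a
  Leff <- min(L, max(avail, 0L))
  if (Leff < 3L) return(list(count = 0L, L_effective = Leff, truncated = Leff < L))
  s <- substr(str, a + 1L, a + Leff)
  offs <- seq_len(Leff - 2L)
  tri <- substring(s, offs, offs + 2L)
  list(count = sum(tri %in% codons), L_effective = Leff, truncated = Leff < L)
}

#' Exact probability of at least one efficient start codon in L nucleotides
#'
#' Dynamic program over a two-nucleotide suffix state for an i.i.d. sequence
#' with the given base composition; the pattern set is `{A,G,T}TG` (any
#' frame, overlaps allowed).
#'
#' @param L sequence length (>= 0).
#' @param base_composition named probabilities for `A`, `C`, `G`, `T`
#'   summing to 1 (default uniform).
#' @return probability in `[0, 1]`; exact and deterministic.
#' @export
start_probability_dp <- function(L, base_composition = c(A = .25, C = .25, G = .25, T = .25)) {
  if (L < 0) stop("L must be >= 0")
  bc <- base_composition[c("A", "C", "G", "T")]
  if (anyNA(bc) || abs(sum(bc) - 1) > 1e-9) stop("base_composition must cover A,C,G,T and sum to 1")
  if (L < 3) return(0)
  bases <- c("A", "C", "G", "T")
  # state = (previous two nucleotides); start: distribution after 2 draws
  states <- as.vector(outer(bases, bases, paste0))  # "XY": X older, Y newer
  prob <- setNames(as.vector(outer(bc, bc)), states)
  for (i in 3:L) {
    nxt <- setNames(numeric(16), states)
    for (st in states) {
      p0 <- prob[[st]]
      if (p0 == 0) next
      x <- substr(st, 1, 1); y <- substr(st, 2, 2)
      for (b in bases) {
        if (y == "T" && b == "G" && x != "C") next  # pattern {A,G,T}TG completed
        nxt[[paste0(y, b)]] <- nxt[[paste0(y, b)]] + p0 * bc[[b]]
      }
    }
    prob <- nxt
  }
  1 - sum(prob)
}

#' Read an operon membership table
#'
#' Tab-separated `operon_id`, `gene_id`, `position_index` (with or without
#' header).
#' @param path TSV path.
#' @return data.frame with those three columns.
#' @export
read_operon_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("operon_id", first, fixed = TRUE)
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) names(df) <- c("operon_id", "gene_id", "position_index")
  df$position_index <- as.integer(df$position_index)
  df
}

#' Read a gene-to-abundance table (TSV: gene_id, abundance)
#' @param path TSV path.
#' @return data.frame `gene_id`, `abundance`.
#' @export
read_abundance_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) names(df) <- c("gene_id", "abundance")
  df$abundance <- as.numeric(df$abundance)
  df
}
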