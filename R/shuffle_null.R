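#' Permute synonymous codons within one coding sequence
#'
#' For each amino acid, the codons encoding it are permuted uniformly among
#' that amino acid's positions; the encoded protein, the codon multiset and
#' the nucleotide composition are all preserved. Codons containing
#' ambiguous bases (`N`) and the terminal stop codon are left in place.
#' Uses the R random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param cds_seq mRNA-sense coding sequence, length divisible by 3.
#' @param translation_table NCBI genetic code id (default 11).
#' @return shuffled sequence (character scalar).
#' @export
shuffle_cds_codons <- function(cds_seq, translation_table = 11L) {
  cds_seq <- toupper(cds_seq)
  len <- nchar(cds_seq)
  if (len %% 3L != 0L) stop("CDS length not divisible by 3")
  cod <- substring(cds_seq, seq(1L, len - 2L, 3L), seq(3L, len, 3L))
  n <- length(cod)
  gc <- Biostrings::getGeneticCode(as.character(translation_table))
  movable <- !grepl("N", cod, fixed = TRUE)
  movable[n] <- FALSE                      # terminal (stop) codon anchored
  aa <- rep(NA_character_, n)
  aa[movable] <- gc[cod[movable]]
  for (fam in split(which(movable), aa[movable])) {
    if (length(fam) > 1L) cod[fam] <- cod[sample(fam)]
  }
  paste(cod, collapse = "")
}

#' Permute the nucleotides of a non-coding sequence
#'
#' Uniform random permutation; the nucleotide multiset is preserved.
#' @param seq character scalar.
#' @return permuted sequence.
#' @export
shuffle_noncoding <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(ch) < 2L) return(seq)
  paste(ch[sample.int(length(ch))], collapse = "")
}

derive_seed <- function(seed, replicate_index) {
  as.integer((as.numeric(seed) * 1000003 + replicate_index) %% 2147483647)
}

#' Composition-preserving randomization of a whole genome
#'
#' The null model behind the local folding bias: synonymous codons are
#' permuted within each coding sequence (minus-strand CDSs are shuffled in
#' mRNA sense, then reverse-complemented back), nucleotides are permuted
#' within each region not covered by any CDS, and nucleotides covered by
#' two or more CDSs are kept byte-identical to the native genome, as are
#' codons containing ambiguous bases and terminal stop codons.
#' Deterministic given `(seed, replicate_index)`.
#'
#' @param genome `DNAStringSet`.
#' @param genes QC-passed gene table.
#' @param seed master seed.
#' @param replicate_index replicate number (each replicate uses an
#'   independent substream).
#' @return `DNAStringSet` of the randomized genome, with a
#'   `replicate_index` and `seed` attribute.
#' @export
randomize_genome <- function(genome, genes, seed, replicate_index = 1L) {
  set.seed(derive_seed(seed, replicate_index))
  out <- genome
  for (ctg in names(genome)) {
    ch <- strsplit(as.character(genome[[ctg]]), "", fixed = TRUE)[[1]]
    L <- length(ch)
    g <- genes[genes$contig_id == ctg, , drop = FALSE]
    cov <- integer(L)
    for (i in seq_len(nrow(g))) {
      idx <- (g$cds_start[i] + 1L):g$cds_end[i]
      cov[idx] <- cov[idx] + 1L
    }
    # CDS codon permutation (mRNA sense), skipping codons touching
    # multiply-covered positions
    for (i in seq_len(nrow(g))) {
      gi <- g[i, ]
      len <- gi$cds_end - gi$cds_start
      if (len %% 3L != 0L) next
      idx <- (gi$cds_start + 1L):gi$cds_end
      sense <- ch[idx]
      if (gi$strand == "-") sense <- comp_chars(rev(sense))
      n <- len %/% 3L
      cod <- vapply(seq_len(n), function(k) paste(sense[(3L * k - 2L):(3L * k)], collapse = ""),
                    character(1))
      # genomic coverage per mRNA codon (orientation does not matter for cov)
      covm <- if (gi$strand == "-") rev(cov[idx]) else cov[idx]
      single <- vapply(seq_len(n), function(k) all(covm[(3L * k - 2L):(3L * k)] == 1L),
                       logical(1))
      movable <- single & !grepl("N", cod, fixed = TRUE)
      movable[n] <- FALSE
      gcode <- Biostrings::getGeneticCode(as.character(gi$translation_table))
      aa <- rep(NA_character_, n)
      aa[movable] <- gcode[cod[movable]]
      aa[movable][is.na(aa[movable])] <- "X"   # codons outside the code table
      for (fam in split(which(movable), aa[movable])) {
        if (length(fam) > 1L) cod[fam] <- cod[sample(fam)]
      }
      sense2 <- strsplit(paste(cod, collapse = ""), "", fixed = TRUE)[[1]]
      if (gi$strand == "-") sense2 <- comp_chars(rev(sense2))
      ch[idx] <- sense2
    }
    # intergenic nucleotide permutation over maximal uncovered runs
    r <- rle(cov == 0L)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths > 1L)) {
      idx <- starts[k]:ends[k]
      ch[idx] <- ch[idx][sample.int(length(idx))]
    }
    out[[ctg]] <- Biostrings::DNAString(paste(ch, collapse = ""))
  }
  attr(out, "replicate_index") <- as.integer(replicate_index)
  attr(out, "seed") <- seed
  out
}

comp_chars <- function(ch) {
  chartr("ACGTN", "TGCAN", ch)
}
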