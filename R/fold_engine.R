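#' Folding engines
#'
#' An engine is a list with `name`, `parameter_set` and a vectorized
#' `fold(seqs)` returning one minimum free energy (MFE, kcal/mol/window)
#' per sequence. Folding is deterministic for a fixed sequence and
#' parameter set, and MFE is never positive (the open chain has energy 0).
#'
#' `vienna_engine()` drives the `RNAfold` executable (Turner parameters,
#' default settings, 37 C) as a batched subprocess; `pairmax_engine()` is a
#' dependency-free base-pair-maximization dynamic program with fixed
#' per-pair energies, intended only for environments without `RNAfold` —
#' its absolute energies are not comparable to Turner-parameter thresholds.
#' `default_engine()` picks `vienna` when available.
#'
#' @param rnafold path to the `RNAfold` executable.
#' @return an object of class `fold_engine`.
#' @name fold_engine
NULL

#' @rdname fold_engine
#' @export
vienna_engine <- function(rnafold = Sys.which("RNAfold")) {
  rnafold <- as.character(rnafold)
  if (!nzchar(rnafold)) stop("RNAfold executable not found on PATH")
  eng <- list(
    name = "vienna",
    parameter_set = "rnafold-default",
    fold = function(seqs) rnafold_batch(rnafold, seqs)
  )
  class(eng) <- "fold_engine"
  eng
}

#' @rdname fold_engine
#' @export
pairmax_engine <- function() {
  eng <- list(
    name = "pairmax",
    parameter_set = "pair-energies GC=-3 AU=-2 GU=-1, minloop 3",
    fold = function(seqs) {
      vapply(seqs, function(s) {
        if (is.na(s)) return(NA_real_)
        pairmax_energy(toupper(s))
      }, numeric(1), USE.NAMES = FALSE)
    }
  )
  class(eng) <- "fold_engine"
  eng
}

#' @rdname fold_engine
#' @export
default_engine <- function() {
  if (nzchar(Sys.which("RNAfold"))) vienna_engine() else pairmax_engine()
}

#' @export
print.fold_engine <- function(x, ...) {
  cat("<fold_engine>", x$name, "|", x$parameter_set, "\n")
  invisible(x)
}

# One subprocess call for a whole batch; duplicates folded once.
rnafold_batch <- function(rnafold, seqs) {
  out <- rep(NA_real_, length(seqs))
  ok <- !is.na(seqs)
  if (!any(ok)) return(out)
  s <- toupper(seqs[ok])
  if (any(!nzchar(s))) stop("empty sequence")
  s <- chartr("T", "U", s)
  uniq <- unique(s)
  res <- system2(rnafold, args = c("--noPS"), input = uniq, stdout = TRUE)
  if (!is.null(attr(res, "status")) && attr(res, "status") != 0)
    stop("RNAfold failed with status ", attr(res, "status"))
  struct_lines <- res[seq(2L, length(res), by = 2L)]
  if (length(struct_lines) != length(uniq)) stop("unexpected RNAfold output")
  m <- regmatches(struct_lines, regexpr("\\(\\s*-?[0-9]+\\.?[0-9]*\\)\\s*$", struct_lines))
  dg <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
  if (length(dg) != length(uniq) || anyNA(dg)) stop("could not parse RNAfold energies")
  out[ok] <- dg[match(s, uniq)]
  out
}

#' Minimum free energy of RNA sequences
#'
#' @param engine a [fold_engine].
#' @param seqs character vector over `{A,C,G,T,U,N}`; `T` is treated as `U`.
#' @return numeric vector of MFE values (kcal/mol), `NA` propagated.
#' @export
mfe <- function(engine, seqs) {
  stopifnot(inherits(engine, "fold_engine"))
  if (length(seqs) == 0L) return(numeric(0))
  if (any(!is.na(seqs) & !nzchar(seqs))) stop("empty sequence")
  bad <- !is.na(seqs) & grepl("[^ACGTUNacgtun]", seqs)
  if (any(bad)) stop("sequence contains non-nucleotide characters")
  engine$fold(seqs)
}

# Windows with more than `max_n_frac` ambiguous bases are skipped (NA).
mask_n_rich <- function(wins, max_n_frac = 0.1) {
  nn <- nchar(gsub("[^N]", "", wins))
  wins[!is.na(wins) & nn / nchar(wins) > max_n_frac] <- NA_character_
  wins
}

#' Sliding-window MFE series around one gene's stop codon
#'
#' Folds every `width`-nt window whose opening position lies in
#' `[p_min, p_max]` on the stop-relative axis. Windows running past the
#' contig end, or with more than 10% ambiguous bases, are omitted.
#'
#' @param engine a [fold_engine].
#' @param gene single gene row (must have passed QC).
#' @param genome `DNAStringSet`.
#' @param width window width, default 40 nt.
#' @param p_min,p_max opening-position range, default `[-100, +100]`.
#' @return object of class `windowed_energy` with `gene_id`, `width`,
#'   `positions`, `dg` and `engine`.
#' @export
window_scan <- function(engine, gene, genome, width = 40L,
                        p_min = -100L, p_max = 100L) {
  ori <- oriented_contigs(genome[gene$contig_id])
  positions <- seq.int(p_min, p_max)
  wins <- extract_window_matrix(gene, ori, positions, width)[1, ]
  wins <- mask_n_rich(wins)
  keep <- !is.na(wins)
  dg <- mfe(engine, wins[keep])
  structure(list(gene_id = gene$gene_id, width = as.integer(width),
                 positions = positions[keep], dg = dg, engine = engine$name),
            class = "windowed_energy")
}

#' Clone-window folding energy for a synthetic operon sequence
#'
#' Folds the single window used to score reporter-library clones: `width`
#' nucleotides starting `offset` nucleotides downstream of the first
#' nucleotide of the (amber, `TAG`) stop codon. Defaults `offset = 9`,
#' `width = 37`; widths in 30-50 are supported for sweeps.
#'
#' @param engine a [fold_engine].
#' @param operon_seq character scalar, mRNA-sense.
#' @param stop_first_nt 1-based index of the stop codon's first nucleotide.
#' @param width window width (default 37).
#' @param offset window start relative to the stop's first nucleotide
#'   (default +9).
#' @return MFE (kcal/mol) of the window.
#' @export
clone_window_dg <- function(engine, operon_seq, stop_first_nt,
                            width = 37L, offset = 9L) {
  operon_seq <- toupper(operon_seq)
  stopifnot(length(operon_seq) == 1L, stop_first_nt >= 1L)
  codon <- substr(operon_seq, stop_first_nt, stop_first_nt + 2L)
  codon <- chartr("U", "T", codon)
  if (codon != "TAG") stop("no TAG stop codon at index ", stop_first_nt,
                           " (found '", codon, "')")
  s0 <- stop_first_nt + offset
  if (s0 + width - 1L > nchar(operon_seq))
    stop("insufficient sequence for a ", width, "-nt window at offset +", offset)
  mfe(engine, substr(operon_seq, s0, s0 + width - 1L))
}
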