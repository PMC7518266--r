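#' Fixed plasmid context for reporter-library clone folding
#'
#' The dual-reporter operon places a 24-nt variable region between the
#' upstream gene's amber stop codon plus a fixed `ACTAGT` hexamer and a
#' fixed downstream reporter prefix beginning `AAGGGCGAGGAGC`. With these
#' defaults the clone window (+9 from the stop's first nucleotide, width
#' 37) is exactly the variable 24-mer followed by the 13-nt suffix.
#'
#' @param flank5 sequence 5' of the variable region, ending at its
#'   boundary; must contain the `TAG` stop whose first nucleotide anchors
#'   the clone window.
#' @param flank3 sequence 3' of the variable region (>= 13 nt by default
#'   usage).
#' @param stop_first_nt 1-based index of the stop codon within `flank5`.
#' @return a `clone_context` list.
#' @export
clone_context <- function(flank5 = "TAGACTAGT",
                          flank3 = "AAGGGCGAGGAGCTCTTTACTG",
                          stop_first_nt = 1L) {
  stopifnot(substr(flank5, stop_first_nt, stop_first_nt + 2L) == "TAG")
  structure(list(flank5 = toupper(flank5), flank3 = toupper(flank3),
                 stop_first_nt = as.integer(stop_first_nt)),
            class = "clone_context")
}

#' The fixed 13-nt suffix completing a 24-nt variable region to 37 nt
#' @export
LIB_SUFFIX_13 <- "AAGGGCGAGGAGC"

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

in_frame_codons <- function(seq) {
  len <- nchar(seq)
  k <- len %/% 3L
  if (k == 0L) return(character(0))
  substring(seq, seq(1L, by = 3L, length.out = k), seq(3L, by = 3L, length.out = k))
}

#' Filter reporter-library variable regions
#'
#' Rejects 24-nt variable regions containing an in-frame stop codon
#' (offsets 0, 3, ..., 21 in the reporter frame) and keeps only those with
#' at least one in-frame efficient start codon.
#'
#' @param reads data.frame with columns `bin_id`, `variable_seq`, `count`.
#' @param starts accepted start codons (default ATG, GTG, TTG).
#' @param stops rejected stop codons (default TAA, TAG, TGA).
#' @return list `kept` (rows of `reads`) and `rejected` (rows plus a
#'   `reason` in `{"internal_stop","no_start"}`); the two partition the
#'   input and re-filtering `kept` is a no-op.
#' @export
filter_variable_reads <- function(reads, starts = START_CODONS,
                                  stops = STOP_CODONS) {
  stopifnot(all(c("bin_id", "variable_seq", "count") %in% names(reads)))
  seqs <- toupper(reads$variable_seq)
  if (any(nchar(seqs) != 24L)) stop("variable regions must be 24 nt")
  if (any(reads$count < 1L)) stop("counts must be >= 1")
  reason <- vapply(seqs, function(s) {
    cod <- in_frame_codons(s)
    if (any(cod %in% stops)) "internal_stop"
    else if (!any(cod %in% starts)) "no_start"
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
  kept <- reads[is.na(reason), , drop = FALSE]
  rejected <- reads[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

# clone-window MFE for a vector of variable regions, batched
variable_region_dg <- function(engine, variable_seqs, context = clone_context(),
                               width = 37L, offset = 9L) {
  seqs <- paste0(context$flank5, toupper(variable_seqs), context$flank3)
  s0 <- context$stop_first_nt + offset
  if (any(s0 + width - 1L > nchar(seqs)))
    stop("clone context too short for a ", width, "-nt window at offset +", offset)
  mfe(engine, substr(seqs, s0, s0 + width - 1L))
}

#' Count-weighted mean clone-window energy of a sorted bin, with bootstrap CI
#'
#' Each unique read is embedded in the fixed plasmid context and scored by
#' [clone_window_dg()] arithmetic; the bin's value is the read-count
#' weighted mean, with a seeded multinomial bootstrap percentile interval
#' (default 99%).
#'
#' @param reads data.frame `bin_id`, `variable_seq`, `count` (one bin).
#' @param engine a [fold_engine].
#' @param ci_level confidence level (default 0.99).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed seed for the bootstrap.
#' @param context a [clone_context()].
#' @return list `mean`, `ci_low`, `ci_high`, `n_reads`, `n_unique`.
#' @export
bin_weighted_dg <- function(reads, engine, ci_level = 0.99, n_boot = 10000L,
                            seed = 1L, context = clone_context()) {
  if (nrow(reads) == 0L) stop("empty bin")
  agg <- tapply(reads$count, toupper(reads$variable_seq), sum)
  seqs <- names(agg); counts <- as.vector(agg)
  dg <- variable_region_dg(engine, seqs, context)
  n <- sum(counts)
  wmean <- sum(counts * dg) / n
  if (length(seqs) == 1L) {
    return(list(mean = wmean, ci_low = wmean, ci_high = wmean,
                n_reads = n, n_unique = 1L))
  }
  set.seed(derive_seed(seed, 0L))
  boots <- rmultinom(n_boot, n, prob = counts / n)
  bmeans <- colSums(boots * dg) / n
  alpha <- (1 - ci_level) / 2
  ci <- unname(quantile(bmeans, c(alpha, 1 - alpha)))
  list(mean = wmean, ci_low = ci[1], ci_high = ci[2],
       n_reads = n, n_unique = length(seqs))
}

#' Per-bin weighted clone-window energies for a whole read table
#'
#' Applies [filter_variable_reads()] then [bin_weighted_dg()] per bin.
#'
#' @inheritParams bin_weighted_dg
#' @param reads data.frame `bin_id`, `variable_seq`, `count` (all bins).
#' @return data.frame `bin_id`, `mean_dg`, `ci_low`, `ci_high`, `n_reads`,
#'   `n_unique`, ordered by `bin_id`.
#' @export
library_bins <- function(reads, engine, ci_level = 0.99, n_boot = 10000L,
                         seed = 1L, context = clone_context()) {
  kept <- filter_variable_reads(reads)$kept
  if (nrow(kept) == 0L) stop("no reads pass filtering")
  out <- do.call(rbind, lapply(split(kept, kept$bin_id), function(b) {
    r <- bin_weighted_dg(b, engine, ci_level, n_boot, seed, context)
    data.frame(bin_id = b$bin_id[1], mean_dg = r$mean, ci_low = r$ci_low,
               ci_high = r$ci_high, n_reads = r$n_reads, n_unique = r$n_unique)
  }))
  out <- out[order(out$bin_id), ]
  rownames(out) <- NULL
  out
}

#' Analytic acceptance probability of the library start/stop filter
#'
#' Probability that a uniform (or composition-weighted) i.i.d. sequence
#' with `n_codons` disjoint in-frame codons contains no stop codon and at
#' least one efficient start codon. In-frame codons are independent, so
#' the result is the closed form
#' `(1 - p_stop)^k - (1 - p_stop - p_start)^k`.
#'
#' @param n_codons number of in-frame codons (8 for a 24-nt variable
#'   region, 12 for a 37-mer).
#' @param base_composition named A/C/G/T probabilities (default uniform).
#' @param starts,stops codon sets.
#' @return acceptance probability.
#' @export
library_acceptance_prob <- function(n_codons,
                                    base_composition = c(A = .25, C = .25, G = .25, T = .25),
                                    starts = START_CODONS, stops = STOP_CODONS) {
  bc <- base_composition[c("A", "C", "G", "T")]
  p_cod <- function(codon) prod(bc[strsplit(codon, "")[[1]]])
  p_start <- sum(vapply(starts, p_cod, numeric(1)))
  p_stop <- sum(vapply(stops, p_cod, numeric(1)))
  (1 - p_stop)^n_codons - (1 - p_stop - p_start)^n_codons
}

random_seqs <- function(n, len, base_composition = c(A = .25, C = .25, G = .25, T = .25)) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(sample(bases, n * len, replace = TRUE, prob = base_composition[bases]),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Simulate a theoretical random clone library and its energy distribution
#'
#' Samples sequences of uniform nucleotide composition under one of three
#' schemes and folds each with the engine:
#' `constrained37` — 37-mers with an in-frame efficient start codon and no
#' in-frame stop; `lib24plus13` — filtered 24-mers concatenated with the
#' fixed suffix `AAGGGCGAGGAGC` (total 37 nt), mimicking the experimental
#' library; `unconstrained` — unfiltered 37-mers.
#'
#' @param scheme sampling scheme.
#' @param n number of accepted sequences to return.
#' @param engine a [fold_engine].
#' @param seed RNG seed.
#' @param starts,stops codon sets for the constrained schemes.
#' @return list `scheme`, `sequences`, `dg`, `acceptance_rate`,
#'   `summary` (mean and quartiles of `dg`).
#' @export
simulate_library <- function(scheme = c("constrained37", "lib24plus13", "unconstrained"),
                             n, engine, seed = 1L,
                             starts = START_CODONS, stops = STOP_CODONS) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 1L)
  set.seed(derive_seed(seed, 0L))
  accepted <- character(0)
  proposed <- 0L
  len <- if (scheme == "lib24plus13") 24L else 37L
  while (length(accepted) < n) {
    batch <- random_seqs(max(n, 1000L), len)
    proposed <- proposed + length(batch)
    if (scheme == "unconstrained") {
      accepted <- c(accepted, batch)
    } else {
      ok <- vapply(batch, function(s) {
        cod <- in_frame_codons(s)
        !any(cod %in% stops) && any(cod %in% starts)
      }, logical(1), USE.NAMES = FALSE)
      accepted <- c(accepted, batch[ok])
    }
  }
  n_accepted <- length(accepted)
  accepted <- accepted[seq_len(n)]
  final <- if (scheme == "lib24plus13") paste0(accepted, LIB_SUFFIX_13) else accepted
  dg <- mfe(engine, final)
  list(scheme = scheme, sequences = final, dg = dg,
       acceptance_rate = if (scheme == "unconstrained") 1 else n_accepted / proposed,
       summary = c(mean = mean(dg), quantile(dg, c(.25, .5, .75))))
}

#' Read a library read table (TSV: bin_id, variable_seq, count)
#' @param path TSV path.
#' @return data.frame `bin_id`, `variable_seq`, `count`.
#' @export
read_library_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("bin_id", first, fixed = TRUE)
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) names(df) <- c("bin_id", "variable_seq", "count")
  df$count <- as.integer(df$count)
  df
}
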