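#' Local folding bias (delta-LFE) profiles for a set of genes
#'
#' For every gene and every window opening position p, computes the native
#' window MFE and the MFE of the same window in `R` composition-preserving
#' randomized genomes ([randomize_genome()]), and reports
#' `dlfe[p] = native_dg[p] - mean_r(rand_dg[r, p])`. Negative delta-LFE
#' means the native mRNA folds more stably than expected under the
#' synonymous-codon-shuffle null. A position is reported only where the
#' native window and all `R` randomized windows are available.
#'
#' All windows from all genes and replicates are folded in one batched
#' engine call.
#'
#' @param genes QC-passed gene table.
#' @param genome `DNAStringSet`.
#' @param engine a [fold_engine].
#' @param R number of randomization replicates (default 20).
#' @param seed master seed for the randomizations.
#' @param width window width (default 40 nt).
#' @param p_range opening-position range, default `c(-100, 100)`.
#' @return object of class `dlfe_set`: a list with `profiles` (one
#'   `dlfe_profile` per gene: `gene_id`, `positions`, `native_dg`,
#'   `rand_dg` (R x P matrix), `dlfe`, `R`) and metadata.
#' @export
dlfe_profiles <- function(genes, genome, engine, R = 20L, seed = 1L,
                          width = 40L, p_range = c(-100L, 100L)) {
  stopifnot(nrow(genes) >= 1L, R >= 1L)
  positions <- seq.int(p_range[1], p_range[2])
  ori <- oriented_contigs(genome)
  native_w <- mask_n_rich(extract_window_matrix(genes, ori, positions, width))
  rand_w <- vector("list", R)
  for (r in seq_len(R)) {
    rg <- randomize_genome(genome, genes, seed, r)
    rand_w[[r]] <- mask_n_rich(extract_window_matrix(genes, oriented_contigs(rg),
                                                     positions, width))
  }
  all_seqs <- c(native_w, unlist(rand_w, use.names = FALSE))
  uniq <- unique(all_seqs[!is.na(all_seqs)])
  dg_map <- setNames(mfe(engine, uniq), uniq)
  lookup <- function(w) {
    m <- matrix(NA_real_, nrow(w), ncol(w), dimnames = dimnames(w))
    ok <- !is.na(w)
    m[ok] <- dg_map[w[ok]]
    m
  }
  native_dg <- lookup(native_w)
  rand_dg <- lapply(rand_w, lookup)

  profiles <- lapply(seq_len(nrow(genes)), function(i) {
    rd <- do.call(rbind, lapply(rand_dg, function(m) unname(m[i, ])))
    ok <- !is.na(native_dg[i, ]) & colSums(is.na(rd)) == 0L
    structure(list(gene_id = genes$gene_id[i],
                   positions = positions[ok],
                   native_dg = unname(native_dg[i, ok]),
                   rand_dg = rd[, ok, drop = FALSE],
                   dlfe = unname(native_dg[i, ok] - colMeans(rd[, ok, drop = FALSE])),
                   R = as.integer(R)),
              class = "dlfe_profile")
  })
  names(profiles) <- genes$gene_id
  structure(list(profiles = profiles, positions = positions,
                 width = as.integer(width), R = as.integer(R),
                 engine = engine$name, seed = seed),
            class = "dlfe_set")
}

#' Delta-LFE profile of a single gene against given randomized genomes
#'
#' @param gene single gene row.
#' @param genome native genome.
#' @param randomized_genomes list of `DNAStringSet`s from
#'   [randomize_genome()].
#' @inheritParams dlfe_profiles
#' @return a `dlfe_profile`.
#' @export
gene_dlfe <- function(gene, genome, randomized_genomes, engine,
                      width = 40L, p_range = c(-100L, 100L)) {
  stopifnot(length(randomized_genomes) >= 1L)
  positions <- seq.int(p_range[1], p_range[2])
  nat <- mask_n_rich(extract_window_matrix(gene, oriented_contigs(genome),
                                           positions, width))[1, ]
  rnd <- lapply(randomized_genomes, function(rg)
    mask_n_rich(extract_window_matrix(gene, oriented_contigs(rg),
                                      positions, width))[1, ])
  seqs <- c(nat, unlist(rnd, use.names = FALSE))
  uniq <- unique(seqs[!is.na(seqs)])
  dg_map <- setNames(mfe(engine, uniq), uniq)
  get <- function(v) unname(ifelse(is.na(v), NA_real_, dg_map[v]))
  native_dg <- get(nat)
  rd <- do.call(rbind, lapply(rnd, get))
  dimnames(rd) <- NULL
  ok <- !is.na(native_dg) & colSums(is.na(rd)) == 0L
  structure(list(gene_id = gene$gene_id, positions = positions[ok],
                 native_dg = native_dg[ok],
                 rand_dg = rd[, ok, drop = FALSE],
                 dlfe = native_dg[ok] - colMeans(rd[, ok, drop = FALSE]),
                 R = length(randomized_genomes)),
            class = "dlfe_profile")
}

#' Aggregate per-gene profiles into per-position landscape summaries
#'
#' @param x a `dlfe_set` (or list of `dlfe_profile`s).
#' @param grouping optional named vector mapping `gene_id` to a group
#'   label; genes missing from the map are dropped. `NULL` puts all genes
#'   in group `"all"`.
#' @param stat which per-gene series to summarise: `"dlfe"` (default) or
#'   `"native"`.
#' @return data.frame `group`, `position`, `n`, `mean`, `median`, `sd`,
#'   `q25`, `q75`.
#' @export
aggregate_landscape <- function(x, grouping = NULL, stat = c("dlfe", "native")) {
  stat <- match.arg(stat)
  profiles <- if (inherits(x, "dlfe_set")) x$profiles else x
  ids <- vapply(profiles, `[[`, character(1), "gene_id")
  if (is.null(grouping)) grouping <- setNames(rep("all", length(ids)), ids)
  keep <- ids %in% names(grouping)[!is.na(grouping)]
  profiles <- profiles[keep]; ids <- ids[keep]
  stopifnot(length(profiles) >= 1L)
  field <- if (stat == "dlfe") "dlfe" else "native_dg"
  long <- do.call(rbind, lapply(profiles, function(p)
    data.frame(gene_id = p$gene_id, position = p$positions, value = p[[field]])))
  long$group <- unname(grouping[long$gene_id])
  agg <- do.call(rbind, lapply(split(long, list(long$group, long$position), drop = TRUE),
    function(d) data.frame(
      group = d$group[1], position = d$position[1], n = nrow(d),
      mean = mean(d$value), median = median(d$value),
      sd = if (nrow(d) > 1L) sd(d$value) else 0,
      q25 = unname(quantile(d$value, .25)), q75 = unname(quantile(d$value, .75)))))
  agg <- agg[order(agg$group, agg$position), ]
  rownames(agg) <- NULL
  agg
}

#' Mean native folding-energy landscape
#'
#' Per-position mean of the native window MFE across genes (no
#' randomization), as in a genome-wide folding-energy scan.
#'
#' @inheritParams dlfe_profiles
#' @return data.frame `position`, `n`, `mean`, `median`, `sd`, `q25`, `q75`.
#' @export
native_landscape <- function(genes, genome, engine, width = 40L,
                             p_range = c(-100L, 100L)) {
  positions <- seq.int(p_range[1], p_range[2])
  w <- mask_n_rich(extract_window_matrix(genes, oriented_contigs(genome),
                                         positions, width))
  uniq <- unique(w[!is.na(w)])
  dg_map <- setNames(mfe(engine, uniq), uniq)
  dg <- matrix(NA_real_, nrow(w), ncol(w))
  dg[!is.na(w)] <- dg_map[w[!is.na(w)]]
  out <- do.call(rbind, lapply(seq_along(positions), function(j) {
    v <- dg[, j]; v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    data.frame(position = positions[j], n = length(v), mean = mean(v),
               median = median(v), sd = if (length(v) > 1L) sd(v) else 0,
               q25 = unname(quantile(v, .25)), q75 = unname(quantile(v, .75)))
  }))
  rownames(out) <- NULL
  out
}

#' Locate the minimum of a landscape under either position convention
#'
#' A fixed-width window scan localizes a structured element at the
#' *centre* of the minimizing window: every window that fully contains a
#' hairpin shorter than the window is near-minimal, so the opening-label
#' argmin sits where the hairpin is centred in the window, displaced
#' 5'-ward of the hairpin's opening by about `(width - element_len) / 2`.
#' Under `convention = "open"` the reported position is the minimizing
#' window's 5' opening (the axis used by the RTS model); under
#' `"center"` it is the window's central nucleotide (`open + width/2`),
#' which estimates the centre of the underlying element.
#'
#' @param landscape data.frame with `position` and `mean` columns
#'   ([aggregate_landscape()] or [native_landscape()] output; pass one
#'   group at a time).
#' @param convention `"open"` or `"center"`.
#' @param width window width used to build the landscape (needed for
#'   `"center"`).
#' @return the argmin position (integer under `"open"`, possibly
#'   half-integer under `"center"`).
#' @export
landscape_minimum <- function(landscape, convention = c("open", "center"),
                              width = 40L) {
  convention <- match.arg(convention)
  p <- landscape$position[which.min(landscape$mean)]
  if (convention == "center") p + (width - 1) / 2 else p
}

#' Write the per-gene delta-LFE profile matrix to TSV (genes x positions)
#' @param dlfe a `dlfe_set`.
#' @param path output file.
#' @export
write_profile_matrix_tsv <- function(dlfe, path) {
  pos <- dlfe$positions
  m <- t(vapply(dlfe$profiles, function(pr)
    pr$dlfe[match(pos, pr$positions)], numeric(length(pos))))
  colnames(m) <- pos
  df <- data.frame(gene_id = names(dlfe$profiles), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a landscape summary to TSV
#' @param landscape data.frame from [aggregate_landscape()].
#' @param path output file.
#' @export
write_landscape_tsv <- function(landscape, path) {
  write.table(landscape, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Abundance quantile grouping for landscape stratification
#'
#' @param abundance data.frame `gene_id`, `abundance`.
#' @param n_quantiles number of quantile bins (default 10 for deciles).
#' @return named character vector gene_id -> `"q01"..`, ordered lowest to
#'   highest abundance.
#' @export
abundance_quantile_groups <- function(abundance, n_quantiles = 10L) {
  br <- quantile(abundance$abundance, probs = seq(0, 1, length.out = n_quantiles + 1L),
                 na.rm = TRUE)
  br[1] <- -Inf; br[length(br)] <- Inf
  q <- cut(abundance$abundance, breaks = unique(br), labels = FALSE,
           include.lowest = TRUE)
  setNames(sprintf("q%02d", q), abundance$gene_id)
}
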