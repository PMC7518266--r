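#' Configuration of the rule-based RTS model
#'
#' Defaults are the model's reference parameter values: a downstream
#' intergenic distance of at least 25 nt (or an opposite-strand / absent
#' neighbour), at least 5 consecutive negative delta-LFE windows opening in
#' [-10, +20], and a native window MFE of at most -6 kcal/mol/window
#' reached inside the qualifying run, with 40-nt windows.
#'
#' @param min_intergenic minimum intergenic distance (nt) for the topology
#'   condition.
#' @param open_range opening-position range of qualifying windows.
#' @param min_run minimum number of consecutive negative delta-LFE windows.
#' @param dg_threshold native MFE threshold (kcal/mol/window).
#' @param width window width (nt).
#' @return an `rts_config` list.
#' @export
rts_config <- function(min_intergenic = 25L, open_range = c(-10L, 20L),
                       min_run = 5L, dg_threshold = -6, width = 40L) {
  stopifnot(min_run >= 1L, open_range[1] <= open_range[2])
  structure(list(min_intergenic = as.integer(min_intergenic),
                 open_range = as.integer(open_range),
                 min_run = as.integer(min_run),
                 dg_threshold = dg_threshold, width = as.integer(width)),
            class = "rts_config")
}

# longest run of TRUE over consecutive integer positions; ties -> 5'-most.
# returns c(start_index, end_index) into `positions`, or NULL.
longest_neg_run <- function(positions, neg, min_run) {
  idx <- which(neg)
  if (!length(idx)) return(NULL)
  grp <- cumsum(c(TRUE, diff(positions[idx]) != 1L | diff(idx) != 1L))
  best <- integer(0)
  for (g in unname(split(idx, factor(grp, levels = unique(grp))))) {
    if (length(g) > length(best)) best <- g
  }
  if (length(best) >= min_run) c(best[1], best[length(best)]) else NULL
}

#' Call the ribosome termination structure for one gene
#'
#' Applies the three-condition model: (1) topology — the gene has no
#' downstream neighbour, or the neighbour is on the opposite strand, or the
#' intergenic distance is at least `min_intergenic`; (2) run — at least
#' `min_run` consecutive windows opening inside `open_range` have strictly
#' negative delta-LFE (the longest such run is selected, 5'-most on ties);
#' (3) depth — within the selected run the native window MFE reaches
#' `dg_threshold` or lower. A gene whose profile does not cover the whole
#' opening range is reported uncallable.
#'
#' @param profile a `dlfe_profile`.
#' @param topology the gene's row from [pair_topology()].
#' @param config an [rts_config()].
#' @param native optional `windowed_energy` to supply native MFEs; by
#'   default the profile's own `native_dg` is used.
#' @return one-row data.frame: `gene_id`, `callable`, `present`,
#'   `cond_topology`, `cond_run`, `cond_depth`, `run_start`, `run_end`,
#'   `min_native_dg_in_run`.
#' @export
call_rts <- function(profile, topology, config = rts_config(), native = NULL) {
  pos <- profile$positions
  dlfe <- profile$dlfe
  ndg <- if (is.null(native)) profile$native_dg else {
    native$dg[match(pos, native$positions)]
  }
  want <- seq.int(config$open_range[1], config$open_range[2])
  sel <- match(want, pos)
  row <- data.frame(gene_id = profile$gene_id, callable = TRUE, present = FALSE,
                    cond_topology = NA, cond_run = NA, cond_depth = NA,
                    run_start = NA_integer_, run_end = NA_integer_,
                    min_native_dg_in_run = NA_real_, stringsAsFactors = FALSE)
  if (anyNA(sel) || anyNA(ndg[sel])) { row$callable <- FALSE; return(row) }
  p <- pos[sel]; d <- dlfe[sel]; nd <- ndg[sel]

  row$cond_topology <- !topology$downstream_exists ||
    !topology$same_strand ||
    topology$intergenic_distance >= config$min_intergenic
  run <- longest_neg_run(p, d < 0, config$min_run)
  row$cond_run <- !is.null(run)
  if (!is.null(run)) {
    idx <- run[1]:run[2]
    row$run_start <- p[run[1]]; row$run_end <- p[run[2]]
    row$min_native_dg_in_run <- min(nd[idx])
    row$cond_depth <- row$min_native_dg_in_run <= config$dg_threshold
  } else {
    row$cond_depth <- FALSE
  }
  row$present <- isTRUE(row$cond_topology) && isTRUE(row$cond_run) &&
    isTRUE(row$cond_depth)
  row
}

#' Call the RTS model over a set of profiles
#'
#' @param dlfe a `dlfe_set` from [dlfe_profiles()].
#' @param topology data.frame from [pair_topology()].
#' @param config an [rts_config()].
#' @return data.frame of per-gene calls (see [call_rts()]).
#' @export
call_rts_all <- function(dlfe, topology, config = rts_config()) {
  rows <- lapply(dlfe$profiles, function(pr) {
    tp <- topology[topology$gene_id == pr$gene_id, , drop = FALSE]
    if (nrow(tp) != 1L) stop("no topology row for gene ", pr$gene_id)
    call_rts(pr, tp, config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of callable genes with an RTS
#'
#' @param calls data.frame from [call_rts_all()].
#' @return list `fraction`, `n_present`, `n_callable`, `n_uncallable`.
#' @export
rts_fraction <- function(calls) {
  callable <- calls[calls$callable, , drop = FALSE]
  if (nrow(callable) == 0L) stop("no callable genes")
  list(fraction = mean(callable$present),
       n_present = sum(callable$present),
       n_callable = nrow(callable),
       n_uncallable = sum(!calls$callable))
}

#' Write RTS calls to TSV
#' @param calls data.frame from [call_rts_all()].
#' @param path output file.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
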