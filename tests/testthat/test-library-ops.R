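test_that("variable-region filter applies the start/stop rules", {
  reads <- data.frame(
    bin_id = "P3",
    variable_seq = c("ATGAAACCCGGGAAACCCGGGAAA",   # in-frame ATG, no stop
                     "AAATAAATGCCCGGGAAACCCGGG",   # in-frame TAA
                     "AAACCCGGGAAACCCGGGAAACCC"),  # no start
    count = c(3L, 2L, 1L))
  f <- filter_variable_reads(reads)
  expect_equal(f$kept$variable_seq, reads$variable_seq[1])
  expect_equal(f$rejected$reason, c("internal_stop", "no_start"))
  # GTG and TTG count as starts; out-of-frame stops do not reject
  ok <- data.frame(bin_id = "P3",
                   variable_seq = c(paste0("GTG", strrep("C", 21)),
                                    paste0("CCC", "TTG", strrep("C", 18)),
                                    paste0("ATG", "CTAAC", strrep("C", 16))),
                   count = 1L)
  expect_equal(nrow(filter_variable_reads(ok)$kept), 3L)
})

test_that("filter is idempotent and partitions the input", {
  set.seed(40)
  lib <- make_library_reads(300, seed = 40)
  f <- filter_variable_reads(lib$reads)
  expect_equal(nrow(f$kept) + nrow(f$rejected), nrow(lib$reads))
  expect_setequal(c(f$kept$variable_seq, f$rejected$variable_seq),
                  lib$reads$variable_seq)
  f2 <- filter_variable_reads(f$kept)
  expect_equal(f2$kept, f$kept)
  expect_equal(nrow(f2$rejected), 0L)
  # filter decisions match the generator's truth flags
  tr <- lib$truth
  kept_truth <- tr$variable_seq[!tr$has_inframe_stop & tr$has_inframe_start]
  expect_setequal(f$kept$variable_seq, kept_truth)
})

test_that("bin weighted mean and bootstrap CI", {
  eng <- test_engine()
  s1 <- paste0("ATG", strrep("C", 21))
  s2 <- paste0("GTG", strrep("A", 21))
  dg <- variable_region_dg(eng, c(s1, s2))
  # independently recompute the embedded clone window
  ctx <- clone_context()
  full <- paste0(ctx$flank5, s1, ctx$flank3)
  expect_equal(dg[1], clone_window_dg(eng, full, 1))

  one <- data.frame(bin_id = "P4", variable_seq = s1, count = 5L)
  r1 <- bin_weighted_dg(one, eng)
  expect_equal(r1$ci_low, r1$mean)
  expect_equal(r1$ci_high, r1$mean)

  two <- data.frame(bin_id = "P4", variable_seq = c(s1, s2), count = c(3L, 1L))
  r2 <- bin_weighted_dg(two, eng, seed = 3)
  expect_equal(r2$mean, (3 * dg[1] + dg[2]) / 4)
  expect_lte(r2$ci_low, r2$mean)
  expect_gte(r2$ci_high, r2$mean)

  # equal counts reduce to the arithmetic mean
  eq <- data.frame(bin_id = "P4", variable_seq = c(s1, s2), count = c(2L, 2L))
  expect_equal(bin_weighted_dg(eq, eng, seed = 3)$mean, mean(dg))

  # splitting a read record leaves the estimate unchanged
  split_rec <- data.frame(bin_id = "P4", variable_seq = c(s1, s1, s2),
                          count = c(2L, 1L, 1L))
  expect_equal(bin_weighted_dg(split_rec, eng, seed = 3),
               bin_weighted_dg(two, eng, seed = 3))
  expect_error(bin_weighted_dg(two[0, ], eng), "empty")
})

test_that("library simulation schemes honour their constraints", {
  eng <- pairmax_engine()   # constraint checks do not need Turner energies
  sim <- simulate_library("lib24plus13", n = 200, engine = eng, seed = 5)
  expect_true(all(endsWith(sim$sequences, "AAGGGCGAGGAGC")))
  expect_true(all(nchar(sim$sequences) == 37L))
  for (s in sim$sequences) {
    cod <- substring(s, seq(1, 22, 3), seq(3, 24, 3))
    expect_false(any(cod %in% c("TAA", "TAG", "TGA")))
    expect_true(any(cod %in% c("ATG", "GTG", "TTG")))
  }
  sim37 <- simulate_library("constrained37", n = 200, engine = eng, seed = 5)
  for (s in sim37$sequences) {
    cod <- substring(s, seq(1, 34, 3), seq(3, 36, 3))
    expect_false(any(cod %in% c("TAA", "TAG", "TGA")))
    expect_true(any(cod %in% c("ATG", "GTG", "TTG")))
  }
  # reproducibility
  sim_b <- simulate_library("constrained37", n = 200, engine = eng, seed = 5)
  expect_identical(sim37$sequences, sim_b$sequences)
  expect_identical(sim37$dg, sim_b$dg)
})

test_that("acceptance rates match the analytic closed form", {
  # closed form against direct enumeration logic at k codons
  expect_equal(library_acceptance_prob(8), (61 / 64)^8 - (58 / 64)^8)
  eng <- pairmax_engine()
  set.seed(41)
  for (case in list(c("lib24plus13", 8), c("constrained37", 12))) {
    sim <- simulate_library(case[1], n = 1000, engine = eng, seed = 11)
    p <- library_acceptance_prob(as.integer(case[2]))
    n_prop <- 1000 / sim$acceptance_rate
    se <- sqrt(p * (1 - p) / n_prop)
    expect_lt(abs(sim$acceptance_rate - p), 3 * se)
  }
})

test_that("filters barely shift the energy distribution", {
  eng <- test_engine()
  unc <- simulate_library("unconstrained", n = 400, engine = eng, seed = 9)
  con <- simulate_library("constrained37", n = 400, engine = eng, seed = 9)
  expect_lte(mean(unc$dg), mean(con$dg) + 1)
})

test_that("per-bin table pipeline on synthetic reads", {
  eng <- test_engine()
  lib <- make_library_reads(200, n_bins = 4, seed = 12, engine = eng)
  res <- library_bins(lib$reads, eng, n_boot = 500, seed = 12)
  expect_true(all(res$ci_low <= res$mean_dg & res$mean_dg <= res$ci_high))
  expect_gte(nrow(res), 3L)
  # energy-sorted bins are monotone in mean dG by construction
  expect_true(all(diff(res$mean_dg[order(res$bin_id)]) >= -1e-9) ||
                all(diff(res$mean_dg[order(res$bin_id)]) <= 1e-9))

  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(lib$reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- read_library_table(path)
  expect_equal(rt, lib$reads)
})
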