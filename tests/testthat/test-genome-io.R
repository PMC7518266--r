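test_that("GFF3 1-based inclusive coordinates become 0-based half-open", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta"); gff <- file.path(dir, "g.gff3")
  writeLines(c(">chr1", "AAACCCGGGTTTAAA"), fa)
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t4\t9\t.\t+\t0\tID=cds1;gene_id=gA"), gff)
  p <- parse_genome(fa, gff)
  expect_equal(p$genes$cds_start, 3L)
  expect_equal(p$genes$cds_end, 9L)
  expect_equal(cds_sequence(p$genes[1, ], p$genome), "CCCGGG")
})

test_that("minus-strand genes read in mRNA sense; multi-part CDS merge", {
  contig <- paste0(strrep("A", 10), "TTACATGGT", strrep("A", 10))
  # forward slice [10,19) = TTACATGGT; gene on minus strand
  genes <- gene_row("gM", 10, 19, strand = "-")
  files <- write_genome_files(contig, genes)
  p <- parse_genome(files$fasta, files$gff)
  expect_equal(cds_sequence(p$genes[1, ], p$genome), "ACCATGTAA")

  gff2 <- file.path(withr::local_tempdir(), "m.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t1\t6\t.\t+\t0\tID=c1;gene_id=gX",
               "chr1\tsrc\tCDS\t10\t15\t.\t+\t0\tID=c2;gene_id=gX"), gff2)
  p2 <- parse_genome(files$fasta, gff2)
  expect_equal(nrow(p2$genes), 1L)
  expect_true(p2$genes$multi_part)
  expect_equal(p2$genes$cds_start, 0L)
  expect_equal(p2$genes$cds_end, 15L)
})

test_that("contig mismatches and out-of-bounds CDS are hard errors", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta"); gff <- file.path(dir, "g.gff3")
  writeLines(c(">chr1", "ACGTACGTACGT"), fa)
  writeLines(c("##gff-version 3",
               "chrZ\tsrc\tCDS\t1\t6\t.\t+\t0\tID=c;gene_id=g"), gff)
  expect_error(parse_genome(fa, gff), "chrZ")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t1\t60\t.\t+\t0\tID=c;gene_id=g"), gff)
  expect_error(parse_genome(fa, gff), "bounds")
})

test_that("QC filter applies the inclusion rules with reasons", {
  set.seed(1)
  mk <- function(seq) {
    contig <- paste0("TTTT", seq, "TTTT")
    genes <- gene_row("g", 4, 4 + nchar(seq))
    genome <- Biostrings::DNAStringSet(c(chr1 = contig))
    qc_filter_genes(genes, genome)
  }
  r <- mk(paste0("ATG", strrep("GCA", 11), "TAA"))   # 39 nt
  expect_equal(r$excluded$reason, "short")
  r <- mk(paste0("ATG", "GCAGCATGAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCA", "TAA")) # 45 nt, internal TGA
  expect_equal(r$excluded$reason, "internal_stop")
  r <- mk(paste0("ATG", strrep("GCA", 13), "TAA"))   # clean 45 nt
  expect_equal(nrow(r$excluded), 0L)
  expect_equal(r$genes$gene_id, "g")
  r <- mk(paste0("ATG", strrep("GCA", 13), "TAAC"))  # 46 nt
  expect_equal(r$excluded$reason, "not_multiple_of_3")
  r <- mk(paste0("ATG", strrep("GCA", 13), "GCA"))   # no stop
  expect_equal(r$excluded$reason, "no_terminal_stop")
})

test_that("sense windows follow the stop-relative axis on both strands", {
  cds <- paste0("ATG", strrep("GCA", 12), "TAA")     # 42 nt, ends ...TAA
  contig <- paste0(strrep("T", 20), cds, "GCAACGT", strrep("T", 20))
  genes <- gene_row("g", 20, 62)
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  expect_equal(sense_window(genes[1, ], genome, 0, 3), "GCA")
  expect_equal(sense_window(genes[1, ], genome, -3, 3), "TAA")
  expect_equal(sense_window(genes[1, ], genome, 1, 4), "CAAC")
  # beyond the contig end -> unavailable, not padded
  expect_true(is.na(sense_window(genes[1, ], genome, 20, 40)))

  fl <- flip_genome(genome, genes)
  for (p in c(-5, -3, 0, 3)) {
    expect_equal(sense_window(fl$genes[1, ], fl$genome, p, 6),
                 sense_window(genes[1, ], genome, p, 6))
  }
})

test_that("pair topology matches the distance conventions", {
  genes <- rbind(gene_row("A", 40, 100), gene_row("B", 125, 185),
                 gene_row("C", 300, 360, strand = "-"))
  tp <- pair_topology(genes)
  expect_equal(tp$next_gene_id[tp$gene_id == "A"], "B")
  expect_equal(tp$intergenic_distance[tp$gene_id == "A"], 25L)
  expect_true(tp$same_strand[tp$gene_id == "A"])
  expect_equal(tp$intergenic_distance[tp$gene_id == "B"], 115L)
  expect_false(tp$same_strand[tp$gene_id == "B"])
  # minus-strand gene looks 5'-ward on the forward strand
  expect_equal(tp$next_gene_id[tp$gene_id == "C"], "B")
  expect_equal(tp$intergenic_distance[tp$gene_id == "C"], 115L)

  ov <- rbind(gene_row("A", 40, 100), gene_row("B", 95, 160))
  expect_equal(pair_topology(ov)$intergenic_distance[1], -5L)

  # translation invariance
  sh <- genes; sh$cds_start <- sh$cds_start + 1000L; sh$cds_end <- sh$cds_end + 1000L
  tp2 <- pair_topology(sh)
  expect_equal(tp2$intergenic_distance, tp$intergenic_distance)

  # nested genes are skipped as "next"
  nest <- rbind(gene_row("A", 40, 200), gene_row("N", 60, 90),
                gene_row("B", 220, 280))
  expect_equal(pair_topology(nest)$next_gene_id[1], "B")
})

test_that("operon position labels are deterministic", {
  genes <- rbind(gene_row("g1", 0, 42), gene_row("g2", 50, 92),
                 gene_row("g3", 100, 142), gene_row("g4", 150, 192),
                 gene_row("g5", 200, 242))
  ops <- data.frame(operon_id = c("o1", "o1", "o1", "o2"),
                    gene_id = c("g1", "g2", "g3", "g4"),
                    position_index = c(1, 2, 3, 1))
  lab <- operon_positions(ops, genes)
  expect_equal(unname(lab[c("g1", "g2", "g3", "g4", "g5")]),
               c("first", "internal", "last", "monocistronic", "unassigned"))
})

test_that("downstream start census counts all frames and matches a regex oracle", {
  down <- paste0("ATGGTG", strrep("C", 44))
  contig <- paste0(strrep("T", 10), "ATGTAA", down)
  genes <- gene_row("g", 10, 16)
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  expect_equal(downstream_start_census(genes[1, ], genome)$count, 2L)

  polyc <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("T", 10), "ATGTAA", strrep("C", 50))))
  expect_equal(downstream_start_census(genes[1, ], polyc)$count, 0L)

  # truncated downstream region
  short <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("T", 10), "ATGTAA", "ATGAA")))
  cs <- downstream_start_census(genes[1, ], short)
  expect_true(cs$truncated)
  expect_equal(cs$L_effective, 5L)
  expect_equal(cs$count, 1L)

  # oracle: overlapping regex scan on 1000 random genes (both strands)
  set.seed(42)
  g <- make_genome(synth_config(n_genes = 1000, gene_len_range = c(14, 40),
                                intergenic_gc = 0.5,
                                frac_opposite_strand = 0.5), seed = 42)
  oracle <- function(s) {
    length(gregexpr("(?=[AGT]TG)", s, perl = TRUE)[[1]]) -
      (gregexpr("(?=[AGT]TG)", s, perl = TRUE)[[1]][1] == -1)
  }
  for (i in sample(nrow(g$genes), 1000)) {
    gene <- g$genes[i, ]
    s <- sense_window(gene, g$genome, 0, 50)
    if (is.na(s)) next
    expect_equal(downstream_start_census(gene, g$genome)$count, oracle(s))
  }
})

test_that("start-codon probability DP is exact, monotone, and matches simulation", {
  expect_equal(start_probability_dp(2), 0)
  expect_equal(start_probability_dp(3), 3 / 64)
  probs <- vapply(0:60, start_probability_dp, numeric(1))
  expect_true(all(diff(probs) >= 0))
  # composition-sensitivity: no T or no G -> probability 0
  expect_equal(start_probability_dp(50, c(A = .5, C = .5, G = 0, T = 0)), 0)

  # exact enumeration oracle over all 4^L sequences at small L
  bases <- c("A", "C", "G", "T")
  for (L in 3:9) {
    idx <- as.matrix(expand.grid(rep(list(1:4), L)))
    m <- matrix(bases[idx], nrow = nrow(idx))
    hit <- rep(FALSE, nrow(m))
    for (i in 1:(L - 2)) {
      hit <- hit | (m[, i] %in% c("A", "G", "T") & m[, i + 1] == "T" & m[, i + 2] == "G")
    }
    expect_equal(start_probability_dp(L), mean(hit))
  }

  # Monte-Carlo oracle at L = 50
  set.seed(7)
  n <- 1e6; L <- 50
  hit <- logical(n)
  for (chunk in split(seq_len(n), rep(1:20, each = n / 20))) {
    m <- matrix(sample(c("A", "C", "G", "T"), length(chunk) * L, replace = TRUE),
                ncol = L)
    h <- rep(FALSE, length(chunk))
    for (i in 1:(L - 2)) {
      h <- h | (m[, i] %in% c("A", "G", "T") & m[, i + 1] == "T" & m[, i + 2] == "G")
    }
    hit[chunk] <- h
  }
  p_mc <- mean(hit)
  p_dp <- start_probability_dp(L)
  se <- sqrt(p_mc * (1 - p_mc) / n)
  expect_lt(abs(p_dp - p_mc), 3 * se)
})
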