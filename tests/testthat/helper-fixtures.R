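# Shared fixtures, built in code at test time.

# Production engine: Turner-parameter RNAfold. The fallback pair-maximizer
# is exercised explicitly where the test is about the engine contract, not
# absolute energies.
test_engine <- local({
  eng <- NULL
  function() {
    if (is.null(eng)) eng <<- vienna_engine()
    eng
  }
})

SENSE_CODONS <- {
  gc <- Biostrings::getGeneticCode("11")
  names(gc)[gc != "*"]
}

random_cds <- function(n_codons, stop = "TAA") {
  paste0("ATG", paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                      collapse = ""), stop)
}

# write a FASTA + GFF3 pair for a single contig and gene table
write_genome_files <- function(contig, genes, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "g.fasta"); gff <- file.path(dir, "g.gff3")
  writeLines(c(">chr1", contig), fa)
  write_gff3(genes, gff)
  list(fasta = fa, gff = gff)
}

gene_row <- function(gene_id, cds_start, cds_end, strand = "+",
                     contig_id = "chr1") {
  data.frame(gene_id = gene_id, contig_id = contig_id, strand = strand,
             cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
             multi_part = FALSE, translation_table = 11L,
             stringsAsFactors = FALSE)
}

# reverse-complement a whole genome and flip all annotations; ids preserved
flip_genome <- function(genome, genes) {
  flipped <- Biostrings::reverseComplement(genome)
  names(flipped) <- names(genome)
  L <- setNames(Biostrings::width(genome), names(genome))
  g2 <- genes
  g2$cds_start <- L[genes$contig_id] - genes$cds_end
  g2$cds_end <- L[genes$contig_id] - genes$cds_start
  g2$strand <- ifelse(genes$strand == "+", "-", "+")
  list(genome = flipped, genes = g2)
}

# hand-constructed delta-LFE profile for caller tests
make_profile <- function(positions, dlfe, native_dg, gene_id = "g") {
  structure(list(gene_id = gene_id, positions = as.integer(positions),
                 native_dg = native_dg,
                 rand_dg = matrix(native_dg - dlfe, nrow = 1),
                 dlfe = dlfe, R = 1L),
            class = "dlfe_profile")
}

topo_row <- function(gene_id = "g", dist = 100L, same = TRUE, exists = TRUE) {
  data.frame(gene_id = gene_id, next_gene_id = if (exists) "x" else NA,
             downstream_exists = exists,
             intergenic_distance = if (exists) as.integer(dist) else NA,
             same_strand = if (exists) same else NA, stringsAsFactors = FALSE)
}

# independent brute-force RTS oracle: enumerate every contiguous window
# interval, keep all-negative ones inside the opening range, pick the
# longest (5'-most on ties), then check depth and topology.
oracle_call_rts <- function(profile, topology, config) {
  want <- seq.int(config$open_range[1], config$open_range[2])
  idx <- match(want, profile$positions)
  stopifnot(!anyNA(idx))
  d <- profile$dlfe[idx]; nd <- profile$native_dg[idx]
  best <- NULL
  for (i in seq_along(want)) for (j in i:length(want)) {
    if (all(d[i:j] < 0)) {
      if (is.null(best) || (j - i) > (best[2] - best[1])) best <- c(i, j)
    }
  }
  cond_run <- !is.null(best) && (best[2] - best[1] + 1L) >= config$min_run
  cond_depth <- cond_run && min(nd[best[1]:best[2]]) <= config$dg_threshold
  cond_topology <- !topology$downstream_exists || !topology$same_strand ||
    topology$intergenic_distance >= config$min_intergenic
  list(present = cond_topology && cond_run && cond_depth,
       cond_run = cond_run,
       run = if (cond_run) want[best] else NULL)
}
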