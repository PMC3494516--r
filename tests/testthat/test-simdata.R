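test_that("configuration invariants are enforced", {
  expect_s3_class(small_sim_config(), "sim_config")
  expect_error(sim_config(read_length_bp = 600L, length_range = c(500L, 900L)),
               "read_length_bp")
  expect_error(sim_config(n_genes = 10L, n_families = 4L, family_size = 3L),
               "n_families")
  expect_error(sim_config(within_family_identity = 0), "identity")
  expect_error(sim_config(frac_expressed = 0), "frac_expressed")
})

test_that("transcriptome simulation builds families and is seed-deterministic", {
  cfg <- sim_config(n_genes = 30L, length_range = c(120L, 300L),
                    n_families = 3L, family_size = 2L,
                    within_family_identity = 1, n_reads = 100L,
                    read_length_bp = 46L, seed = 5L)
  tx <- simulate_transcriptome(cfg)
  expect_equal(nrow(tx$genes), 30L)
  expect_equal(tx$genes$length_bp, unname(nchar(tx$sequences)))
  # identity 1: family members are exact duplicates
  for (f in 1:3) {
    members <- tx$sequences[which(tx$family == f)]
    expect_length(members, 2L)
    expect_identical(unname(members[1L]), unname(members[2L]))
  }
  expect_identical(simulate_transcriptome(cfg), tx)

  part <- sim_config(n_genes = 30L, length_range = c(120L, 300L),
                     n_families = 1L, family_size = 2L,
                     within_family_identity = 0.9, n_reads = 100L, seed = 5L)
  tx2 <- simulate_transcriptome(part)
  fam <- tx2$sequences[which(tx2$family == 1L)]
  ident <- mean(strsplit(fam[[1L]], "")[[1L]] == strsplit(fam[[2L]], "")[[1L]])
  expect_gt(ident, 0.8)
  expect_lt(ident, 1)
})

test_that("without families no 46-mer is shared between genes", {
  cfg <- sim_config(n_genes = 40L, length_range = c(150L, 250L),
                    n_families = 0L, n_reads = 100L, seed = 13L)
  tx <- simulate_transcriptome(cfg)
  idx <- kmer_index(tx$sequences, 46L)
  expect_identical(anyDuplicated(idx$kmer), 0L)
})

test_that("expression truth is sparse, log-normal and exact where zero", {
  cfg <- sim_config(n_genes = 1000L, length_range = c(100L, 200L),
                    n_families = 0L, frac_expressed = 0.5, n_reads = 100L,
                    seed = 3L)
  tx <- simulate_transcriptome(cfg)
  truth <- assign_expression(tx$genes, cfg)
  expect_identical(sum(truth$weight > 0), 500L)   # round(frac * n), exact
  expect_true(all(truth$weight[truth$weight <= 0] == 0))

  all_on <- assign_expression(tx$genes,
                              sim_config(n_genes = 1000L,
                                         length_range = c(100L, 200L),
                                         n_families = 0L, frac_expressed = 1,
                                         n_reads = 100L, seed = 3L))
  expect_true(all(all_on$weight > 0))
})

test_that("reads are exact substrings with origin encoded and conserved", {
  cfg <- small_sim_config(seed = 17L, n_reads = 5000L, n_genes = 50L)
  tx <- simulate_transcriptome(cfg)
  truth <- assign_expression(tx$genes, cfg)
  rd <- simulate_reads(tx$sequences, truth, cfg)
  expect_length(rd$reads, 5000L)
  expect_identical(sum(rd$truth$origin_reads), 5000L)
  expect_true(all(rd$truth$origin_reads[rd$truth$weight == 0] == 0L))
  # spot-check name encoding and substring fidelity
  parts <- strsplit(names(rd$reads)[1:200], "|", fixed = TRUE)
  for (i in seq_along(parts)) {
    gene <- parts[[i]][2L]
    off <- as.integer(parts[[i]][3L])
    expect_identical(unname(substr(tx$sequences[[gene]], off + 1L, off + 46L)),
                     unname(rd$reads[i]))
  }
})

test_that("a single expressed gene takes every read and its exact true RPKM", {
  cfg <- sim_config(n_genes = 5L, length_range = c(200L, 200L),
                    n_families = 0L, frac_expressed = 0.2, n_reads = 1000L,
                    seed = 23L)
  tx <- simulate_transcriptome(cfg)
  truth <- assign_expression(tx$genes, cfg)
  expect_identical(sum(truth$weight > 0), 1L)
  rd <- simulate_reads(tx$sequences, truth, cfg)
  on <- rd$truth$weight > 0
  expect_identical(rd$truth$origin_reads[on], 1000L)
  expect_equal(rd$truth$true_rpkm[on], compute_rpkm(1000, 200, 1000))
  expect_true(all(rd$truth$true_rpkm[!on] == 0))
})

test_that("origin counts follow the expression weights (binomial oracle)", {
  cfg <- sim_config(n_genes = 2L, length_range = c(500L, 500L),
                    n_families = 0L, frac_expressed = 1, n_reads = 10000L,
                    seed = 29L)
  tx <- simulate_transcriptome(cfg)
  truth <- data.frame(gene = tx$genes$name, weight = c(2, 1))
  rd <- simulate_reads(tx$sequences, truth, cfg)
  p <- 2 / 3   # equal lengths, weights 2:1
  expect_lt(abs(rd$truth$origin_reads[1L] / 10000 - p),
            4 * sqrt(p * (1 - p) / 10000))
  expect_error(simulate_reads(tx$sequences,
                              data.frame(gene = tx$genes$name, weight = c(0, 0)),
                              cfg),
               "zero")
})

test_that("exact-match alignment reports every occurrence, matching a brute-force scan", {
  cfg <- sim_config(n_genes = 20L, length_range = c(150L, 400L),
                    n_families = 2L, family_size = 2L,
                    within_family_identity = 1, frac_expressed = 1,
                    n_reads = 300L, seed = 37L)
  sim <- simulate_dataset(cfg)
  reads <- suppressMessages(parse_bowtie_output(sim$alignments, sim$genes))
  expect_identical(reads$n_reads, 300L)
  expect_identical(reads$n_alignments, length(sim$alignments))

  # brute-force quadratic substring scan as the independent oracle
  brute <- 0L
  for (r in seq_along(sim$reads)) {
    for (g in seq_along(sim$sequences)) {
      m <- gregexpr(sim$reads[[r]], sim$sequences[[g]], fixed = TRUE)[[1L]]
      if (m[1L] != -1L) brute <- brute + length(m)
    }
  }
  expect_identical(length(sim$alignments), brute)

  # reads from the conserved region of an exact-duplicate pair hit both copies
  fam_genes <- sim$genes$name[which(sim$family == 1L)]
  origin <- vapply(strsplit(names(sim$reads), "|", fixed = TRUE), `[`,
                   character(1), 2L)
  from_fam <- which(origin == fam_genes[1L])
  if (length(from_fam) > 0L) {
    aln_per_read <- tabulate(reads$alignments$read, reads$n_reads)
    expect_true(all(aln_per_read[from_fam] >= 2L))
  }
})

test_that("FASTA and truth outputs round-trip", {
  cfg <- small_sim_config(seed = 41L, n_reads = 500L, n_genes = 20L)
  sim <- simulate_dataset(cfg)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sim$sequences, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(back), sim$sequences)
  tt <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(sim$truth, tt)
  expect_equal(read_truth_table(tt), sim$truth, tolerance = 1e-6)
})
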