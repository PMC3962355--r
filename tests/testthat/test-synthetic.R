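test_that("generators are deterministic given the seed", {
  cfg <- sim_config(seed = 7, n_hairpins = 5, reads_median = 30)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_records(g1$genome, f1, "fasta")
  write_records(g2$genome, f2, "fasta")
  expect_identical(readLines(f1), readLines(f2))

  r1 <- simulate_reads(g1$genome, g1$truth, cfg)
  r2 <- simulate_reads(g2$genome, g2$truth, cfg)
  expect_identical(r1, r2)

  o1 <- simulate_ontology(cfg)
  o2 <- simulate_ontology(cfg)
  expect_identical(o1$annotations, o2$annotations)
  expect_identical(o1$study, o2$study)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_hairpins = 0), "positive")
  expect_error(sim_config(mature_len = 16), ">= 18")
  expect_error(sim_config(loop_len = 2), ">= 3")
  expect_error(sim_config(pirna_fraction = 1.2), "fractions")
  expect_error(sim_config(enriched_term_effect = 1), "exceed 1")
  expect_error(simulate_ontology(sim_config(n_go_terms = 2)), "at least 3")
})

test_that("planted hairpin windows fold back on themselves", {
  cfg <- sim_config(seed = 8, n_hairpins = 10)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$truth), 10)
  for (i in seq_len(nrow(g$truth))) {
    tr <- g$truth[i, ]
    ctg <- g$genome$seq[g$genome$id == tr$contig]
    win <- substr(ctg, tr$hp_start + 1, tr$hp_end)
    if (tr$strand == "-") win <- revcomp(win)
    f <- fold_hairpin(win)
    paired <- sum(f$partner[1:22] > 0)
    expect_gte(paired / 22, 0.6)
  }
})

test_that("read labels are conserved and arms behave as configured", {
  cfg <- sim_config(seed = 9, n_hairpins = 4, reads_median = 60,
                    five_prime_purity = 1, noise_read_fraction = 0,
                    pirna_fraction = 0, n_rescue = 0)
  g <- simulate_genome(cfg)
  lib <- simulate_reads(g$genome, g$truth, cfg)
  expect_equal(nrow(lib$reads), nrow(lib$labels))
  expect_setequal(unique(lib$labels$origin), c("mature", "star", "loop"))

  # with full purity and no noise, every mapped read lies inside a hairpin
  qc <- run_qc(lib$reads, qc_params())
  aln <- map_reads(qc$reads, g$genome)
  # palindromic arm reads can map up to 2 nt outside the planted span
  for (i in seq_len(nrow(aln))) {
    tr <- g$truth[g$truth$contig == aln$contig[i], ]
    expect_gte(aln$start[i], tr$hp_start - 2)
    expect_lte(aln$end[i], tr$hp_end + 2)
  }
  # all mature-arm reads share one 5' coordinate per hairpin (judged on
  # the planted strand; palindromic extra loci sit on the other strand)
  mat_ids <- lib$labels$id[lib$labels$origin == "mature"]
  for (j in seq_len(nrow(g$truth))) {
    tr <- g$truth[j, ]
    ma <- aln[aln$read_id %in% mat_ids & aln$contig == tr$contig &
                aln$strand == tr$strand, ]
    p5 <- ifelse(ma$strand == "+", ma$start, ma$end - 1)
    expect_true(all(p5 == tr$mature5))
  }
})

test_that("the piRNA fraction carries the designed 5'-U bias", {
  cfg <- sim_config(seed = 10, n_hairpins = 10, reads_median = 130,
                    pirna_fraction = 0.7)
  g <- simulate_genome(cfg)
  lib <- simulate_reads(g$genome, g$truth, cfg)
  pi <- lib$reads[lib$labels$origin == "pirna", ]
  expect_gt(nrow(pi), 5000)
  frac_t <- mean(substr(pi$seq, 1, 1) == "T")
  expect_lt(abs(frac_t - 0.9), 0.03)
  expect_true(all(nchar(pi$seq) == cfg$instrument_len))  # adapter-filled
})

test_that("an adapter is required when inserts need filling", {
  cfg <- sim_config(seed = 11, n_hairpins = 2, reads_median = 20)
  cfg$adapter3 <- ""
  g <- simulate_genome(cfg)
  expect_error(simulate_reads(g$genome, g$truth, cfg), "adapter3 required")
})

test_that("decoy windows carry stacks but no designed structure", {
  cfg <- sim_config(seed = 12)
  dec <- simulate_decoys(10, cfg, reads_per_decoy = 20)
  expect_equal(nrow(dec$genome), 10)
  expect_equal(nrow(dec$reads), 200)
  expect_equal(nrow(dec$truth), 10)
})
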