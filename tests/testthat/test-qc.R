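mk_read <- function(seq, quals) {
  data.frame(id = "r", seq = seq, qual = phred_encode(quals),
             stringsAsFactors = FALSE)
}

test_that("quality_trim strips the low-quality 3' run, strictly at 20", {
  r <- quality_trim(mk_read("ACGTA", c(30, 30, 25, 20, 15)))
  expect_equal(r$seq, "ACG")
  expect_equal(nchar(r$qual), 3)

  r <- quality_trim(mk_read("ACG", c(40, 40, 40)))
  expect_equal(r$seq, "ACG")

  r <- quality_trim(mk_read("AC", c(10, 5)))
  expect_equal(r$seq, "")
  expect_equal(r$qual, "")
})

test_that("expected_error_rate is the mean per-base error probability", {
  expect_equal(expected_error_rate(phred_encode(rep(20, 7))), 0.01)
  expect_equal(expected_error_rate(phred_encode(rep(13, 10))), 10^-1.3,
               tolerance = 1e-12)
  expect_equal(expected_error_rate(phred_encode(c(40, 40, 10))),
               (1e-4 + 1e-4 + 0.1) / 3, tolerance = 1e-12)
  expect_error(expected_error_rate(""), "empty")
})

test_that("trim_adapters removes 3' adapter suffixes and is idempotent", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  params <- qc_params(adapter3 = ad)
  insert <- "ACATCGTCAGACTCAC"
  full <- mk_read(paste0(insert, ad), rep(35, nchar(insert) + nchar(ad)))
  expect_equal(trim_adapters(full, params)$seq, insert)

  part <- mk_read(paste0(insert, substr(ad, 1, 3)), rep(35, nchar(insert) + 3))
  expect_equal(trim_adapters(part, params)$seq, insert)

  clean <- mk_read("ACATCGTCAGACTCAC", rep(35, 16))
  expect_equal(trim_adapters(clean, params)$seq, clean$seq)

  set.seed(3)
  reads <- random_reads(60)
  once <- trim_adapters(reads, params)
  expect_identical(trim_adapters(once, params), once)
})

test_that("5' adapters are trimmed symmetrically", {
  params <- qc_params(adapter3 = "TGGAATTCTCGGG", adapter5 = "GTTCAGAGTT")
  r <- mk_read(paste0("GTTCAGAGTT", "ACATCGTCAGACT"), rep(35, 23))
  expect_equal(trim_adapters(r, params)$seq, "ACATCGTCAGACT")
})

test_that("contaminant_filter drops k-mer sharers on either strand", {
  contam <- contaminant_records()
  frag <- substr(contam$seq[1], 101, 125)
  reads <- data.frame(
    id = c("hit", "rc_hit", "clean"),
    seq = c(frag, revcomp(substr(contam$seq[1], 501, 523)),
            "GATTTACAGCCTCTTACAGCAG"),
    qual = c(phred_encode(rep(35, 25)), phred_encode(rep(35, 23)),
             phred_encode(rep(35, 22))),
    stringsAsFactors = FALSE)
  kept <- contaminant_filter(reads, contam, k = 21)
  expect_equal(kept$id, "clean")
  expect_error(contaminant_filter(reads, contam, k = 2000), "shortest")
})

test_that("run_qc applies all five filters in order", {
  # identity pipeline: perfect quals, adapter that cannot chance-match
  set.seed(8)
  clean <- data.frame(id = sprintf("c%d", 1:20),
                      seq = replicate(20, random_seq(25, c("A", "G", "T"))),
                      qual = rep(phred_encode(rep(40, 25)), 20),
                      stringsAsFactors = FALSE)
  res <- run_qc(clean, qc_params(adapter3 = "CCCCCCCCCC"))
  expect_equal(res$reads$seq, clean$seq)
  expect_true(all(res$report$counts == 20))

  # read kept by 3' trimming but with mean Phred below 20 -> discarded
  low <- mk_read(random_seq(20), c(rep(15, 19), 40))
  expect_equal(nrow(run_qc(low, qc_params())$reads), 0)

  # a 9-nt read fails the 10-bp length floor
  short <- mk_read(random_seq(9), rep(40, 9))
  expect_equal(nrow(run_qc(short, qc_params())$reads), 0)

  # reads containing N are dropped at the error-rate stage
  nread <- mk_read("ACGTNACGTACGT", rep(40, 13))
  expect_equal(nrow(run_qc(nread, qc_params())$reads), 0)
})

test_that("run_qc survivors re-pass every predicate; funnel is monotone", {
  set.seed(21)
  reads <- random_reads(400, qmin = 5, qmax = 41)
  params <- qc_params()
  res <- run_qc(reads, params, contaminant_records())
  expect_true(all(diff(res$report$counts) <= 0))
  for (i in seq_len(nrow(res$reads))) {
    q <- phred_scores(res$reads$qual[i])
    expect_gt(q[length(q)], params$min_tail_phred)
    expect_gt(mean(q), params$min_mean_phred)
    expect_lte(expected_error_rate(res$reads$qual[i]), params$max_error_rate)
    expect_gte(nchar(res$reads$seq[i]), params$min_len)
    expect_false(grepl("N", res$reads$seq[i], fixed = TRUE))
  }
  # both retention conventions are reported
  expect_true(res$report$kept_fraction_counting_empty_as_kept >=
                res$report$kept_fraction_excluding_empty)
})

test_that("composition_table counts first bases per length row", {
  reads <- data.frame(id = c("a", "b", "c"),
                      seq = c(paste0("T", random_seq(25)),
                              paste0("T", random_seq(25)),
                              paste0("A", random_seq(25))),
                      qual = NA, stringsAsFactors = FALSE)
  tab <- composition_table(reads)
  expect_equal(tab$length, 26)
  expect_equal(tab$frac_T, 2 / 3)
  expect_equal(tab$frac_A, 1 / 3)
  expect_equal(nrow(composition_table(reads[0, ])), 0)
})
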