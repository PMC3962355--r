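test_that("longest_orf scans three frames with 5'-most tie-breaking", {
  orf <- longest_orf("AAATGGCCTAAGG")
  expect_equal(c(orf$start, orf$end, orf$length), c(2, 11, 9))

  expect_null(longest_orf("CCCCCC"))

  # two equal-length ORFs: the 5'-most wins
  two <- paste0("ATGAAATAA", "C", "ATGCCCTAA")
  orf <- longest_orf(two)
  expect_equal(orf$start, 0)

  # no stop codon: ORF runs to the transcript end
  orf <- longest_orf("CCATGAAAAAAAAA")
  expect_equal(orf$end, 14)
})

test_that("extract_utr3 keeps suffixes of at least 100 nt", {
  tx <- paste0(strrep("C", 10), "ATG", strrep("AAC", 20), "TAA",
               strrep("T", 150))
  orf <- longest_orf(tx)
  expect_equal(nchar(extract_utr3(tx, orf)), 150)

  tx99 <- paste0(strrep("C", 10), "ATG", strrep("AAC", 20), "TAA",
                 strrep("T", 99))
  expect_null(extract_utr3(tx99, longest_orf(tx99)))
  expect_null(extract_utr3(tx, NULL))
})

test_that("seed_matches finds reverse-complement seed sites", {
  # seed of positions 2-8 of the miR-100-family mature is cccguag,
  # whose reverse complement is CTACGGG
  mat <- spi_matures()
  m <- mat$seq[mat$id == "spi-miR-temp-1"]
  utr <- paste0(strrep("A", 40), "CTACGGG", strrep("A", 60))
  expect_equal(seed_matches(m, utr), 41L)

  expect_equal(length(seed_matches(m, strrep("A", 100))), 0)

  # overlapping occurrences are all reported
  m2 <- "CTTTTTTTAGCAGCAGCAGCAG"   # seed TTTTTTT -> site AAAAAAA
  expect_equal(seed_matches(m2, strrep("A", 10)), 1:4)

  expect_error(seed_matches("ACGTACG", "AAAA"), "shorter")
})

test_that("duplex_dG sums the per-pair model over seed plus extension", {
  # seed cccguag: C,C,C,G,U,A,G = 3 G:C pairs + G:C + A:U + U:A + G:C
  # = 5 GC + 2 AU = -19; flanking mismatches stop the extension
  m <- "acccguagauccgaacuugugg"
  site7 <- "CTACGGG"
  utr <- paste0(strrep("C", 30), site7, strrep("C", 30))  # C blocks both ends
  s <- seed_matches(m, utr)
  d <- duplex_dG(m, utr, s)
  expect_equal(d$dg, -19)
  expect_equal(c(d$site_start, d$site_end), c(31, 37))

  # a perfect 22-nt complement with 10 GC and 12 AU pairs scores -54 at
  # the full-duplex registration (the GC run admits shifted seed matches)
  m2 <- paste0(strrep("GC", 5), strrep("AT", 6))
  utr2 <- paste0(strrep("T", 20), revcomp(m2), strrep("T", 80))
  d2 <- lapply(seed_matches(m2, utr2), function(s) duplex_dG(m2, utr2, s))
  dgs <- vapply(d2, `[[`, 0, "dg")
  expect_equal(min(dgs), -(10 * 3 + 12 * 2))
  best <- d2[[which.min(dgs)]]
  expect_equal(best$site_end - best$site_start + 1, 22)
})

test_that("open_cost is the energy difference of constrained folding", {
  # pairing-free context: poly-A flanks, C-only site, nothing can pair
  utr <- paste0(strrep("A", 60), strrep("C", 7), strrep("A", 60))
  expect_equal(open_cost(utr, 61, 67), 0)

  # a site forming one strand of a 5-pair G:C stem costs 15 to open
  utr2 <- paste0(strrep("A", 40), "CCCCC", "AAAA", "GGGGG", strrep("A", 60))
  expect_equal(open_cost(utr2, 50, 54), 15)

  # opening cost is never negative and ddG is never below dG_duplex
  set.seed(61)
  for (i in 1:15) {
    u <- random_seq(180)
    m <- random_seq(22)
    for (s in seed_matches(m, u)) {
      d <- duplex_dG(m, u, s)
      oc <- open_cost(u, d$site_start, d$site_end)
      expect_gte(oc, 0)
      expect_gte(d$dg + oc, d$dg)
    }
  }
})

test_that("predict_targets applies the ddG cutoff with monotone retention", {
  cfg <- sim_config(seed = 62, n_hairpins = 4, n_rescue = 0,
                    n_strong = 3, n_weak = 3, n_short_utr = 1)
  g <- simulate_genome(cfg)
  tx <- simulate_transcripts(
    data.frame(id = g$truth$hairpin, seq = g$truth$mature_seq), cfg)
  utrs <- extract_all_utrs(tx$transcripts)
  expect_true(all(nchar(utrs$seq) >= 100))
  # short-UTR transcripts are excluded
  expect_false(any(tx$truth$id[tx$truth$class == "short_utr"] %in% utrs$id))

  mat <- data.frame(id = g$truth$hairpin, seq = g$truth$mature_seq)
  t10 <- predict_targets(mat, utrs, cutoff = -10)
  expect_true(all(t10$retained == (t10$ddg <= -10)))
  expect_true(all(t10$open_cost >= 0))
  expect_true(all(t10$dg_duplex <= 0))
  expect_true(!is.unsorted(t10$ddg))

  # retention is monotone in the cutoff
  t20 <- predict_targets(mat, utrs, cutoff = -20)
  key <- function(d) paste(d$mirna, d$transcript, d$utr_start)
  expect_true(all(key(t20[t20$retained, ]) %in% key(t10[t10$retained, ])))
})
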