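test_that("map_reads finds exact matches on both strands and applies rules", {
  set.seed(41)
  genome <- data.frame(id = "c1", desc = "", seq = random_seq(2000))
  insert <- "GATTTACAGCCTCTTACAGCAG"
  genome$seq <- paste0(genome$seq, revcomp(insert), random_seq(100))
  reads <- data.frame(id = c("minus", "short", "multi"),
                      seq = c(insert, substr(insert, 1, 15), "A"),
                      stringsAsFactors = FALSE)
  aln <- map_reads(reads, genome)
  expect_equal(aln$read_id, "minus")
  expect_equal(aln$strand, "-")
  expect_equal(substr(genome$seq, aln$start + 1, aln$end), revcomp(insert))

  # a read at 6 loci produces no alignments; at 5 it is kept
  rep6 <- paste(rep("ACGTAGCATGCAAGCTTACG", 1), collapse = "")
  g6 <- data.frame(id = "c1", desc = "",
                   seq = paste(c(replicate(6, random_seq(50)), ""),
                               collapse = rep6))
  expect_equal(nrow(map_reads(data.frame(id = "r", seq = rep6), g6)), 0)
  g5 <- data.frame(id = "c1", desc = "",
                   seq = paste(c(replicate(5, random_seq(50)), ""),
                               collapse = rep6))
  expect_equal(nrow(map_reads(data.frame(id = "r", seq = rep6), g5)), 5)
  expect_error(map_reads(reads, genome[0, ]), "empty genome")
})

test_that("mapping agrees with a naive substring oracle", {
  set.seed(42)
  cfg <- sim_config(seed = 42, n_hairpins = 8, reads_median = 40)
  g <- simulate_genome(cfg)
  lib <- simulate_reads(g$genome, g$truth, cfg)
  reads <- unique(lib$reads[, c("seq", "id")])[1:300, ]
  got <- map_reads(reads, g$genome)
  want <- naive_map(reads, g$genome)
  got <- got[order(got$read_id, got$contig, got$start, got$strand),
             c("read_id", "contig", "start", "end", "strand")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("call_stacks merges nearby 5' ends and applies the count floor", {
  mk <- function(p5, n, len = 22)
    data.frame(read_id = sprintf("r%d_%d", p5, seq_len(n)),
               seq = strrep("A", len), contig = "c1", start = p5,
               end = p5 + len, strand = "+", copies = 1)
  aln <- rbind(mk(100, 80), mk(101, 15), mk(99, 5))
  st <- call_stacks(aln)
  expect_equal(nrow(st), 1)
  expect_equal(st$modal5, 100)
  expect_equal(st$total, 100)
  expect_equal(st$consistency, 0.8)

  st <- call_stacks(rbind(mk(100, 20), mk(150, 20)))
  expect_equal(nrow(st), 2)

  expect_equal(nrow(call_stacks(mk(100, 9))), 0)
})

test_that("excise_precursors cuts two windows with the right geometry", {
  set.seed(43)
  genome <- data.frame(id = "c1", desc = "", seq = random_seq(1000))
  stack <- data.frame(contig = "c1", strand = "+", modal5 = 500,
                      modal_len = 22, total = 50, consistency = 0.9,
                      span_start = 498, span_end = 524)
  w <- excise_precursors(stack, genome, flank = 70)
  expect_equal(nrow(w), 2)
  expect_equal(nchar(w$seq), c(92, 92))
  a <- w[w$window == "A", ]
  expect_equal(c(a$start, a$end), c(500, 592))
  expect_equal(a$mature_offset, 0)
  b <- w[w$window == "B", ]
  expect_equal(c(b$start, b$end), c(430, 522))
  expect_equal(b$mature_offset, 70)

  # near the contig start the upstream window is clipped or skipped
  stack$modal5 <- 10
  expect_message(w <- excise_precursors(stack, genome, flank = 70),
                 "skipping")
  expect_true(all(w$start >= 0))
})

test_that("duplex_metrics recovers designed Dicer geometry", {
  cfg <- sim_config(seed = 44, n_hairpins = 2, n_rescue = 0)
  g <- simulate_genome(cfg)
  tr <- g$truth[1, ]
  ctg <- g$genome[g$genome$id == tr$contig, ]
  # construct the stack and alignments by hand from truth
  mk_aln <- function(p5, n, len)
    data.frame(read_id = sprintf("x%d_%d", p5, seq_len(n)),
               seq = strrep("N", len), contig = tr$contig, start = p5,
               end = p5 + len, strand = "+", copies = 1)
  aln <- rbind(mk_aln(tr$mature5, 80, 22), mk_aln(tr$mature5 + 1, 15, 22),
               mk_aln(tr$mature5 - 1, 5, 22), mk_aln(tr$star5, 20, 22))
  stack <- call_stacks(aln)
  stack <- stack[stack$modal5 == tr$mature5, ]
  wins <- excise_precursors(stack, g$genome)
  a <- wins[wins$window == "A", ]
  m <- duplex_metrics(a, fold_hairpin(a$seq), aln)
  expect_equal(m$overhang3, 2)
  expect_equal(m$overhang3_mature, 2)
  expect_equal(m$overhang3_star, 2)
  expect_equal(m$five_prime_consistency, 0.8)
  expect_equal(m$stem_mismatches, 2L)       # the 2-nt overhang is unpaired
  expect_equal(m$mature_paired_fraction, 20 / 22)
  expect_equal(m$mature_count, 100L)
  expect_equal(m$star_count, 20L)
})

test_that("a 3-nt-overhang precursor is measured as overhang 3", {
  cfg <- sim_config(seed = 45, n_hairpins = 2, n_rescue = 2)
  g <- simulate_genome(cfg)
  tr <- g$truth[1, ]
  expect_equal(tr$overhang, 3L)
  mk_aln <- function(p5, n, len)
    data.frame(read_id = sprintf("x%d_%d", p5, seq_len(n)),
               seq = strrep("N", len), contig = tr$contig, start = p5,
               end = p5 + len, strand = "+", copies = 1)
  aln <- rbind(mk_aln(tr$mature5, 50, 22), mk_aln(tr$star5, 15, 23))
  stack <- call_stacks(aln)
  stack <- stack[stack$modal5 == tr$mature5, ]
  wins <- excise_precursors(stack, g$genome)
  a <- wins[wins$window == "A", ]
  m <- duplex_metrics(a, fold_hairpin(a$seq), aln)
  expect_equal(m$overhang3, 3)
  expect_equal(m$overhang3_mature, 2)
  expect_equal(m$overhang3_star, 3)
})

test_that("score_candidate follows the documented formula", {
  m <- list(mature_count = 511, star_count = 3, mature_paired_fraction = 0.9)
  expect_equal(score_candidate(m), 9 + 3 + 4.5)
  m <- list(mature_count = 3, star_count = 0, mature_paired_fraction = 0.5)
  expect_equal(score_candidate(m), 2 + 0 + 2.5)
  m <- list(mature_count = 0, star_count = 0, mature_paired_fraction = 0)
  expect_equal(score_candidate(m), 0)
})

test_that("classify applies all criteria and the conservation rescue", {
  good <- structure(list(valid = TRUE, mature_count = 500L, star_count = 5L,
                         loop_count = 0L, overhang3 = 2,
                         overhang3_mature = 2, overhang3_star = 2,
                         five_prime_consistency = 0.9,
                         stem_mismatches = 2L,
                         mature_paired_fraction = 0.9),
                    class = "hairpin_metrics")
  shifted <- good; shifted$overhang3 <- 3
  hit <- data.frame(query = "q", subject = "nve-miR-2022", offset = 1,
                    overlap = 21, mismatches = 2, family = "miR-2022")
  v <- classify(c("a", "b", "c"), list(good, shifted, shifted),
                list(hit[0, ], hit, hit[0, ]))
  expect_equal(v$passed, c(TRUE, TRUE, FALSE))
  expect_equal(v$rescued_by_conservation, c(FALSE, TRUE, FALSE))
  expect_equal(v$failed, c("", "overhang", "overhang"))

  # a 4-nt overhang is beyond rescue even with a hit
  far <- good; far$overhang3 <- 4
  v <- classify("d", list(far), list(hit))
  expect_false(v$passed)

  # verdict consistency invariant: passed implies no failures or rescue
  expect_true(all(!v$passed | v$failed == "" | v$rescued_by_conservation))
})
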