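test_that("read_fasta parses records, concatenates lines and normalises", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT"), p)
  r <- read_fasta(p)
  expect_equal(r$id, "x")
  expect_equal(r$seq, "ACGT")

  writeLines(c(">x", "AC", "GT", ">y d", "TTTT"), p)
  r <- read_fasta(p)
  expect_equal(nrow(r), 2)
  expect_equal(r$seq[1], "ACGT")
  expect_equal(r$desc[2], "d")

  writeLines(c(">x", "acgu"), p)
  expect_equal(read_fasta(p)$seq, "ACGT")   # RNA input -> upper-case DNA
})

test_that("read_fasta rejects malformed input with located errors", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "AC!T"), p)
  expect_error(read_fasta(p), "line 2")
  writeLines(character(0), p)
  expect_error(read_fasta(p), "empty")
  writeLines(c("ACGT", ">x", "AC"), p)
  expect_error(read_fasta(p), "before first header")
})

test_that("read_fastq decodes Phred+33 and enforces record structure", {
  p <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), p)
  expect_equal(phred_scores(read_fastq(p)$qual), rep(40L, 4))

  writeLines(c("@r1", "ACG", "+", "!5I"), p)
  expect_equal(phred_scores(read_fastq(p)$qual), c(0L, 20L, 40L))

  writeLines(c("@r1", "ACGT", "+", "III"), p)
  expect_error(read_fastq(p), "length mismatch")

  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "AC"), p)
  expect_error(read_fastq(p), "divisible by 4")

  # Phred+64-style qualities (chars below '!') must fail loudly
  writeLines(c("@r1", "ACGT", "+", "II I"), p)
  expect_error(read_fastq(p), "below")
})

test_that("FASTA and FASTQ writing round-trips 1000 random records", {
  set.seed(11)
  reads <- random_reads(1000)
  fq <- withr::local_tempfile(fileext = ".fq")
  write_records(reads, fq, "fastq")
  back <- read_fastq(fq)
  expect_equal(back$id, reads$id)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)

  fa <- withr::local_tempfile(fileext = ".fa")
  recs <- data.frame(id = reads$id, desc = "", seq = reads$seq)
  write_records(recs, fa, "fasta")
  back <- read_fasta(fa)
  expect_equal(back$seq, reads$seq)

  # degenerate cases
  write_records(reads[0, ], fa, "fasta")
  expect_equal(length(readLines(fa)), 0)
  expect_error(write_records(recs, fq, "fastq"), "qual")
})

test_that("parse_obo builds a DAG, drops obsolete terms, detects cycles", {
  p <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "name: parent", "",
               "[Term]", "id: GO:2", "name: child", "is_a: GO:1 ! parent",
               "", "[Term]", "id: GO:3", "name: gone",
               "is_obsolete: true"), p)
  dag <- parse_obo(p)
  expect_setequal(dag$terms, c("GO:1", "GO:2"))
  expect_equal(ancestors(dag, "GO:2"), "GO:1")
  expect_equal(dag$roots, "GO:1")

  writeLines(c("[Term]", "id: GO:1", "is_a: GO:2", "",
               "[Term]", "id: GO:2", "is_a: GO:1"), p)
  expect_error(parse_obo(p), "cycle")

  writeLines(c("[Term]", "id: GO:1", "is_a: GO:9"), p)
  expect_error(parse_obo(p), "unknown term")

  writeLines(c("[Term]", "name: anonymous"), p)
  expect_error(parse_obo(p), "lacks an id")
})

test_that("ancestor sets are transitively closed on a random DAG", {
  set.seed(5)
  onto <- simulate_ontology(sim_config(seed = 5, n_go_terms = 25))
  dag <- onto$dag
  for (t in dag$terms) {
    anc <- ancestors(dag, t)
    for (p in dag$parents[[t]]) {
      expect_true(p %in% anc)
      expect_true(all(ancestors(dag, p) %in% anc))
    }
  }
})
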