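# Independent oracles and fixture builders used across the suite.

# exhaustive maximum-weight nested pairing, plain recursion (no memo, no
# traceback) -- independent of the C++ dynamic program
oracle_fold_score <- function(seq) {
  w <- function(a, b) {
    if (a == "T") a <- "U"; if (b == "T") b <- "U"
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) return(3)
    if (p %in% c("AU", "UA")) return(2)
    if (p %in% c("GU", "UG")) return(1)
    0
  }
  s <- strsplit(toupper(seq), "")[[1]]
  rec <- function(i, j) {
    if (j - i < 4) return(0)
    best <- rec(i, j - 1)
    for (k in i:(j - 4)) {
      pw <- w(s[k], s[j])
      if (pw == 0) next
      left <- if (k > i) rec(i, k - 1) else 0
      best <- max(best, pw + left + rec(k + 1, j - 1))
    }
    best
  }
  rec(1, length(s))
}

# naive exact mapping by substring scan on both strands
naive_map <- function(reads, genome, min_len = 18, max_loci = 5) {
  rc <- function(x) coralmir::revcomp(x)
  find_all <- function(pat, subject) {
    hits <- gregexpr(paste0("(?=", pat, ")"), subject, perl = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits)
  }
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    if (nchar(s) < min_len || grepl("N", s, fixed = TRUE)) next
    hits <- list()
    for (ci in seq_len(nrow(genome))) {
      for (p in find_all(s, genome$seq[ci]))
        hits[[length(hits) + 1]] <- data.frame(
          contig = genome$id[ci], start = p - 1L,
          end = p - 1L + nchar(s), strand = "+")
      for (p in find_all(rc(s), genome$seq[ci]))
        hits[[length(hits) + 1]] <- data.frame(
          contig = genome$id[ci], start = p - 1L,
          end = p - 1L + nchar(s), strand = "-")
    }
    if (length(hits) == 0 || length(hits) > max_loci) next
    for (h in hits) {
      h$read_id <- reads$id[i]
      rows[[length(rows) + 1]] <- h
    }
  }
  if (length(rows) == 0)
    return(data.frame(read_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$read_id, out$contig, out$start, out$strand),
      c("read_id", "contig", "start", "end", "strand")]
}

# exact hypergeometric survival by log-choose summation
hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  if (length(i) == 0 || k > min(n, K)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# random reads with random Phred+33 qualities
random_reads <- function(n, len_range = c(15, 35), qmin = 0, qmax = 41) {
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  data.frame(
    id = sprintf("r%04d", seq_len(n)),
    seq = vapply(len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""), ""),
    qual = vapply(len, function(l)
      intToUtf8(sample(qmin:qmax, l, TRUE) + 33L), ""),
    stringsAsFactors = FALSE)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

contaminant_records <- function() {
  read_fasta(system.file("extdata", "synthetic_contaminants.fasta",
                         package = "coralmir"))
}

known_reference <- function() {
  read_fasta(system.file("extdata", "known_mirnas_synthetic.fasta",
                         package = "coralmir"))
}

spi_matures <- function() {
  read_fasta(system.file("extdata", "spi_matures.fasta",
                         package = "coralmir"))
}

# a small in-code ontology: root A <- B <- C (leaf), plus root A <- D
tiny_dag <- function() {
  structure(list(
    terms = c("GO:A", "GO:B", "GO:C", "GO:D"),
    names = c("GO:A" = "root", "GO:B" = "mid", "GO:C" = "leaf",
              "GO:D" = "other"),
    parents = list("GO:A" = character(0), "GO:B" = "GO:A",
                   "GO:C" = "GO:B", "GO:D" = "GO:A"),
    roots = "GO:A"), class = "ontology_dag")
}
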