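# Small-RNA read quality control.
#
# Stage order follows the library-cleaning protocol for GA2x small-RNA data:
# 3' quality trimming, mean-quality and expected-error filtering (2% cap),
# adapter trimming, contaminant k-mer removal, and a minimum-length filter.
# Thresholds written as ">20" are strict: a terminal base at Phred 20 is
# trimmed and a read whose mean Phred is exactly 20 fails.

#' QC parameter set
#'
#' @param min_tail_phred 3' trimming threshold; trailing bases with Phred
#'   `<= min_tail_phred` are removed (default 20).
#' @param min_mean_phred reads with mean Phred `<= min_mean_phred` after
#'   trimming are discarded (default 20).
#' @param max_error_rate cap on the mean per-base error probability computed
#'   from the Phred scores (default 0.02).
#' @param adapter3,adapter5 adapter sequences; `adapter5` may be `NULL`.
#' @param adapter_min_overlap minimum adapter overlap in nt (default 3).
#' @param adapter_max_error allowed mismatch fraction in the adapter overlap
#'   (default 0.1).
#' @param min_len minimum surviving read length (default 10).
#' @param contaminant_k k-mer size for contaminant matching (default 21).
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(min_tail_phred = 20, min_mean_phred = 20,
                      max_error_rate = 0.02,
                      adapter3 = "TGGAATTCTCGGGTGCCAAGG", adapter5 = NULL,
                      adapter_min_overlap = 3, adapter_max_error = 0.1,
                      min_len = 10, contaminant_k = 21) {
  stopifnot(min_tail_phred > 0, min_mean_phred > 0, max_error_rate > 0,
            min_len >= 1, adapter_min_overlap >= 1, contaminant_k >= 1)
  structure(list(min_tail_phred = min_tail_phred,
                 min_mean_phred = min_mean_phred,
                 max_error_rate = max_error_rate,
                 adapter3 = if (is.null(adapter3)) NULL else norm_dna(adapter3),
                 adapter5 = if (is.null(adapter5)) NULL else norm_dna(adapter5),
                 adapter_min_overlap = adapter_min_overlap,
                 adapter_max_error = adapter_max_error,
                 min_len = min_len, contaminant_k = contaminant_k),
            class = "qc_params")
}

#' Trim low-quality 3' ends
#'
#' Removes trailing bases while the terminal base's Phred score is
#' `<= min_tail_phred`. The result may be empty (later removed by the length
#' filter).
#'
#' @param reads read data.frame (`id`, `seq`, `qual`).
#' @param min_tail_phred trimming threshold.
#' @return the reads with trimmed `seq`/`qual`.
#' @export
quality_trim <- function(reads, min_tail_phred = 20) {
  keep_len <- vapply(reads$qual, function(q) {
    s <- phred_scores(q)
    ok <- which(s > min_tail_phred)
    if (length(ok) == 0) 0L else max(ok)
  }, integer(1), USE.NAMES = FALSE)
  reads$seq <- substr(reads$seq, 1, keep_len)
  reads$qual <- substr(reads$qual, 1, keep_len)
  reads
}

#' Expected error rate of a read
#'
#' The mean per-base error probability derived from the Phred scores:
#' `sum(10^(-Q/10)) / length`.
#'
#' @param qual a Phred+33 quality string (non-empty).
#' @return the expected per-base error rate.
#' @export
expected_error_rate <- function(qual) {
  if (nchar(qual) == 0)
    stop("expected_error_rate is undefined for an empty read", call. = FALSE)
  q <- phred_scores(qual)
  mean(10^(-q / 10))
}

# best adapter trim point for one read end; returns new [start, end] indices
trim_one_end <- function(seq, adapter, min_overlap, max_error, end3 = TRUE) {
  n <- nchar(seq)
  na <- nchar(adapter)
  if (n < min_overlap) return(c(1L, n))
  sv <- seq_chars(seq)
  av <- seq_chars(adapter)
  if (end3) {
    # read suffix vs adapter prefix; earliest start = longest overlap
    for (s in seq_len(n - min_overlap + 1)) {
      w <- min(n - s + 1L, na)
      mm <- sum(sv[s:(s + w - 1L)] != av[1:w])
      if (mm <= floor(max_error * w)) return(c(1L, s - 1L))
    }
    c(1L, n)
  } else {
    # read prefix vs adapter suffix; latest end = longest overlap
    for (e in n:min_overlap) {
      if (e > n) next
      w <- min(e, na)
      mm <- sum(sv[(e - w + 1L):e] != av[(na - w + 1L):na])
      if (mm <= floor(max_error * w)) return(c(e + 1L, n))
    }
    c(1L, n)
  }
}

#' Trim adapter sequence from reads
#'
#' The best (longest) 3'-suffix match to a prefix of `adapter3` with at least
#' `adapter_min_overlap` nt and mismatch fraction `<= adapter_max_error` is
#' removed; the symmetric rule applies to `adapter5` at the 5' end. Trimming
#' is applied 3' first, then 5', and repeated until no further match exists,
#' so the operation is idempotent. Qualities are trimmed in step.
#'
#' @param reads read data.frame.
#' @param params a [qc_params()] object (adapters and tolerances).
#' @return trimmed reads.
#' @export
trim_adapters <- function(reads, params = qc_params()) {
  if (nrow(reads) == 0) return(reads)
  for (i in seq_len(nrow(reads))) {
    repeat {
      s <- reads$seq[i]
      n0 <- nchar(s)
      if (n0 == 0) break
      lo <- 1L; hi <- n0
      if (!is.null(params$adapter3)) {
        r <- trim_one_end(substr(s, lo, hi), params$adapter3,
                          params$adapter_min_overlap,
                          params$adapter_max_error, end3 = TRUE)
        hi <- lo + r[2] - 1L
      }
      if (!is.null(params$adapter5) && hi >= lo) {
        r <- trim_one_end(substr(s, lo, hi), params$adapter5,
                          params$adapter_min_overlap,
                          params$adapter_max_error, end3 = FALSE)
        lo <- lo + r[1] - 1L
      }
      if (hi - lo + 1L == n0) break
      reads$seq[i] <- substr(reads$seq[i], lo, hi)
      reads$qual[i] <- substr(reads$qual[i], lo, hi)
    }
  }
  reads
}

# k-mer set of a sequence vector, both strands
kmer_set <- function(seqs, k) {
  out <- character(0)
  for (s in c(seqs, revcomp(seqs))) {
    n <- nchar(s)
    if (n < k) next
    out <- c(out, substring(s, 1:(n - k + 1), k:n))
  }
  unique(out)
}

#' Remove reads sharing k-mers with contaminant sequences
#'
#' A read is dropped iff it shares at least one exact k-mer (either strand)
#' with any contaminant sequence; survivor order is preserved. Stands in for
#' assemble-then-BLAST rRNA/tRNA/mRNA removal with a direct, offline check.
#'
#' @param reads read data.frame.
#' @param contaminants data.frame of contaminant records ([read_fasta()]).
#' @param k k-mer size; must not exceed the shortest contaminant.
#' @return the surviving reads.
#' @export
contaminant_filter <- function(reads, contaminants, k = 21) {
  if (nrow(contaminants) == 0)
    stop("contaminant set is empty", call. = FALSE)
  if (k > min(nchar(contaminants$seq)))
    stop("k exceeds the shortest contaminant sequence", call. = FALSE)
  bad_kmers <- kmer_set(contaminants$seq, k)
  hit <- vapply(reads$seq, function(s) {
    n <- nchar(s)
    if (n < k) return(FALSE)
    any(substring(s, 1:(n - k + 1), k:n) %in% bad_kmers)
  }, logical(1), USE.NAMES = FALSE)
  reads[!hit, , drop = FALSE]
}

#' Run the full QC pipeline
#'
#' Stages, in order: 3' quality trimming; mean-Phred and expected-error
#' filtering (reads containing N are discarded here, as their error rate is
#' undefined); adapter trimming; contaminant removal; minimum length.
#'
#' @param reads read data.frame from [read_fastq()].
#' @param params a [qc_params()] object.
#' @param contaminants optional contaminant records; `NULL` skips the stage.
#' @return list with `reads` (the survivors) and `report` (a `qc_report`:
#'   stage counts plus the length-by-first-base composition table).
#' @export
run_qc <- function(reads, params = qc_params(), contaminants = NULL) {
  counts <- c(raw = nrow(reads))
  reads <- quality_trim(reads, params$min_tail_phred)
  n_emptied <- sum(nchar(reads$seq) == 0)
  counts["post_trim_nonempty"] <- nrow(reads) - n_emptied
  reads <- reads[nchar(reads$seq) > 0, , drop = FALSE]

  ok <- !grepl("N", reads$seq, fixed = TRUE)
  mean_q <- rep(NA_real_, nrow(reads))
  err <- rep(NA_real_, nrow(reads))
  for (i in which(ok)) {
    q <- phred_scores(reads$qual[i])
    mean_q[i] <- mean(q)
    err[i] <- mean(10^(-q / 10))
  }
  keep <- ok & mean_q > params$min_mean_phred & err <= params$max_error_rate
  reads <- reads[keep, , drop = FALSE]
  counts["post_error"] <- nrow(reads)

  reads <- trim_adapters(reads, params)
  reads <- reads[nchar(reads$seq) > 0, , drop = FALSE]
  counts["post_adapter"] <- nrow(reads)

  if (!is.null(contaminants)) {
    reads <- contaminant_filter(reads, contaminants, params$contaminant_k)
  }
  counts["post_contaminant"] <- nrow(reads)

  # final sweep: adapter trimming can shift a read's quality profile, so the
  # mean-quality and error predicates are re-checked on the emitted reads
  keep <- nchar(reads$seq) >= params$min_len
  for (i in which(keep)) {
    q <- phred_scores(reads$qual[i])
    keep[i] <- mean(q) > params$min_mean_phred &&
      mean(10^(-q / 10)) <= params$max_error_rate
  }
  reads <- reads[keep, , drop = FALSE]
  counts["post_length"] <- nrow(reads)

  report <- structure(
    list(counts = counts,
         n_emptied_by_trimming = n_emptied,
         kept_fraction_excluding_empty = counts[["post_length"]] /
           counts[["raw"]],
         kept_fraction_counting_empty_as_kept =
           (counts[["post_length"]] + n_emptied) / counts[["raw"]],
         composition = composition_table(reads)),
    class = "qc_report")
  list(reads = reads, report = report)
}

#' Length-by-first-nucleotide composition table
#'
#' One row per observed read length in 10-39 nt, with counts and fractions of
#' the 5'-terminal base. The 26-31 nt rows of a small-RNA library with a
#' piRNA fraction show a characteristic 5'-U (here T) excess.
#'
#' @param reads cleaned read data.frame.
#' @return data.frame with columns `length`, `A`, `C`, `G`, `T`, `n` and
#'   `frac_A` .. `frac_T`.
#' @export
composition_table <- function(reads) {
  empty <- data.frame(length = integer(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), n = integer(0),
                      frac_A = numeric(0), frac_C = numeric(0),
                      frac_G = numeric(0), frac_T = numeric(0))
  if (nrow(reads) == 0) return(empty)
  len <- nchar(reads$seq)
  sel <- len >= 10 & len <= 39
  if (!any(sel)) return(empty)
  len <- len[sel]
  first <- factor(substr(reads$seq[sel], 1, 1), levels = c("A", "C", "G", "T"))
  tab <- table(length = len, first)
  out <- data.frame(length = as.integer(rownames(tab)),
                    A = as.integer(tab[, "A"]), C = as.integer(tab[, "C"]),
                    G = as.integer(tab[, "G"]), T = as.integer(tab[, "T"]))
  out$n <- out$A + out$C + out$G + out$T
  for (b in c("A", "C", "G", "T")) out[[paste0("frac_", b)]] <- out[[b]] / out$n
  out
}
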