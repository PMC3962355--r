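# Hairpin-based miRNA discovery.
#
# Cleaned reads are mapped exactly (both strands, <= 5 genomic loci), read
# stacks with homogeneous 5' ends nominate candidate precursors, two windows
# around each stack are excised and folded, and Dicer-geometry metrics
# (3' overhang of the mature:star duplex, 5'-end consistency, stem
# mismatches) decide which candidates are bona fide miRNAs. A candidate whose
# only failure is a 3-nt 3' overhang can be rescued by a conservation hit.

#' Map reads exactly to a genome
#'
#' Only exact full-length matches are reported, on both strands. Reads
#' shorter than `min_len` or occurring at more than `max_loci` genomic
#' positions produce no alignments (the multi-locus rule guards against
#' repetitive elements).
#'
#' @param reads read data.frame (`id`, `seq`).
#' @param genome genome records ([read_fasta()] data.frame).
#' @param min_len minimum read length to map (default 18).
#' @param max_loci maximum genomic occurrences (default 5).
#' @return data.frame of alignments: `read_id`, `seq`, `contig`, `start`,
#'   `end` (0-based half-open, forward-strand coordinates), `strand`,
#'   `copies`.
#' @export
map_reads <- function(reads, genome, min_len = 18, max_loci = 5) {
  if (nrow(genome) == 0) stop("empty genome", call. = FALSE)
  subject <- Biostrings::DNAStringSet(setNames(genome$seq, genome$id))
  keep <- nchar(reads$seq) >= min_len & !grepl("N", reads$seq, fixed = TRUE)
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0)
    return(data.frame(read_id = character(0), seq = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      copies = integer(0)))
  uniq <- unique(reads$seq)
  per_seq <- vector("list", length(uniq))
  for (u in seq_along(uniq)) {
    s <- uniq[u]
    rows <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") s else revcomp(s)
      m <- Biostrings::vmatchPattern(pat, subject)
      for (ci in seq_along(subject)) {
        ir <- m[[ci]]
        if (length(ir) == 0) next
        rows[[length(rows) + 1]] <- data.frame(
          contig = genome$id[ci],
          start = BiocGenerics::start(ir) - 1L,
          end = BiocGenerics::end(ir),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    hits <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(hits) && nrow(hits) <= max_loci) {
      hits$copies <- nrow(hits)
      per_seq[[u]] <- hits
    }
  }
  names(per_seq) <- uniq
  out <- list()
  for (i in seq_len(nrow(reads))) {
    hits <- per_seq[[reads$seq[i]]]
    if (is.null(hits)) next
    hits$read_id <- reads$id[i]
    hits$seq <- reads$seq[i]
    out[[length(out) + 1]] <- hits
  }
  if (length(out) == 0)
    return(data.frame(read_id = character(0), seq = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      copies = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("read_id", "seq", "contig", "start", "end", "strand", "copies")]
}

# 5' genomic coordinate of an alignment (0-based): start on +, end - 1 on -
align_five_prime <- function(aln) {
  ifelse(aln$strand == "+", aln$start, aln$end - 1L)
}

#' Call read stacks from alignments
#'
#' Alignments on the same contig/strand whose 5' positions lie within
#' `merge_gap` of each other are merged into one stack; stacks supported by
#' fewer than `min_count` reads are dropped.
#'
#' @param alignments from [map_reads()].
#' @param min_count minimum reads per stack (default 10).
#' @param merge_gap maximum 5'-position gap merged into one stack (default 2).
#' @return data.frame of stacks: `contig`, `strand`, `modal5` (0-based
#'   genomic 5' position), `modal_len`, `total`, `consistency` (fraction of
#'   stack reads sharing the modal 5' end), `span_start`, `span_end`.
#' @export
call_stacks <- function(alignments, min_count = 10, merge_gap = 2) {
  empty <- data.frame(contig = character(0), strand = character(0),
                      modal5 = integer(0), modal_len = integer(0),
                      total = integer(0), consistency = numeric(0),
                      span_start = integer(0), span_end = integer(0))
  if (nrow(alignments) == 0) return(empty)
  alignments$p5 <- align_five_prime(alignments)
  out <- list()
  for (key in unique(paste(alignments$contig, alignments$strand))) {
    grp <- alignments[paste(alignments$contig, alignments$strand) == key, ]
    pos <- sort(unique(grp$p5))
    cluster <- cumsum(c(1L, diff(pos) > merge_gap))
    for (cl in unique(cluster)) {
      members <- grp[grp$p5 %in% pos[cluster == cl], ]
      hist <- table(members$p5)
      modal5 <- as.integer(names(hist)[which.max(hist)])
      modal_reads <- members[members$p5 == modal5, ]
      len_tab <- table(nchar(modal_reads$seq))
      out[[length(out) + 1]] <- data.frame(
        contig = members$contig[1], strand = members$strand[1],
        modal5 = modal5,
        modal_len = as.integer(names(len_tab)[which.max(len_tab)]),
        total = nrow(members),
        consistency = max(hist) / nrow(members),
        span_start = min(members$start), span_end = max(members$end),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[res$total >= min_count, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Excise candidate precursor windows around a stack
#'
#' Two windows are cut, each anchored on the modal read: window A runs from
#' the modal 5' end downstream (`mature_len + flank`), window B runs from the
#' modal 3' end upstream; a genuine hairpin lies inside one of the two.
#' Windows are clipped at contig ends and skipped (with a message) when
#' shorter than the minimal foldable hairpin.
#'
#' @param stack one row of [call_stacks()] output.
#' @param genome genome records.
#' @param flank nt of genomic context beyond the mature arm (default 70).
#' @return data.frame of candidate windows: `window` ("A"/"B"), `contig`,
#'   `start`, `end`, `strand`, `seq` (strand-adjusted, 5'->3'),
#'   `mature_offset` (0-based offset of the mature arm in `seq`),
#'   `mature_len`, `clipped`.
#' @export
excise_precursors <- function(stack, genome, flank = 70) {
  ctg <- genome$seq[genome$id == stack$contig]
  if (length(ctg) != 1) stop("stack contig not in genome", call. = FALSE)
  L <- nchar(ctg)
  mlen <- stack$modal_len
  min_window <- mlen + 3 + 15
  # genomic span of the modal read
  if (stack$strand == "+") {
    m_start <- stack$modal5
    m_end <- stack$modal5 + mlen
  } else {
    m_end <- stack$modal5 + 1L
    m_start <- m_end - mlen
  }
  windows <- list()
  add_window <- function(tag, g_start, g_end) {
    clipped <- g_start < 0 || g_end > L
    g_start <- max(0L, g_start)
    g_end <- min(L, as.integer(g_end))
    if (g_end - g_start < min_window) {
      message(sprintf("skipping %s window at %s:%d (%d nt < %d nt minimum)",
                      tag, stack$contig, g_start, g_end - g_start,
                      min_window))
      return()
    }
    s <- substr(ctg, g_start + 1, g_end)
    if (stack$strand == "-") s <- revcomp(s)
    off <- if (stack$strand == "+") m_start - g_start else g_end - m_end
    windows[[length(windows) + 1]] <<- data.frame(
      window = tag, contig = stack$contig, start = g_start, end = g_end,
      strand = stack$strand, seq = s, mature_offset = as.integer(off),
      mature_len = mlen, clipped = clipped, stringsAsFactors = FALSE)
  }
  # window A: mature arm 5' of the hairpin (stem-loop extends 3' of it)
  # window B: mature arm 3' of the hairpin
  if (stack$strand == "+") {
    add_window("A", m_start, m_start + mlen + flank)
    add_window("B", m_end - mlen - flank, m_end)
  } else {
    add_window("A", m_end - mlen - flank, m_end)
    add_window("B", m_start, m_start + mlen + flank)
  }
  if (length(windows) == 0) return(NULL)
  do.call(rbind, windows)
}

# mature positions paired outside the mature span, with partners restricted
# to the dominant partner cluster (within one mature length of the median
# partner) so isolated long-range pairs do not distort the star span
duplex_pairs <- function(partner, m1, m2, mature_len) {
  n <- length(partner)
  outside <- which(seq_len(n) >= m1 & seq_len(n) <= m2 &
                     partner > 0 & (partner < m1 | partner > m2))
  if (length(outside) == 0) return(NULL)
  partners <- partner[outside]
  med <- stats::median(partners)
  core <- abs(partners - med) <= mature_len
  if (!any(core)) return(NULL)
  list(mature = outside[core], partners = partners[core])
}

#' Dicer-geometry metrics for a folded candidate
#'
#' The mature arm is the stack's modal read; the star arm extent is taken
#' from star-mapping reads when present (the read-delimited precursor is
#' then refolded, excluding flank context that is not part of the duplex),
#' and otherwise from the span of the mature arm's pairing partners.
#' Metrics: the 3' overhang of each duplex strand (reported as
#' `overhang3 = max` of the two; the mature-side and star-side values are
#' both kept), the fraction of mature-arm reads sharing the modal 5' end,
#' the number of mature bases without a partner in the star arm (stem
#' mismatches), and per-arm read counts.
#'
#' @param candidate one row of [excise_precursors()] output.
#' @param fold result of [fold_hairpin()] on `candidate$seq`.
#' @param alignments alignments overlapping the candidate's genomic window
#'   (same contig/strand).
#' @return a list of class `hairpin_metrics`.
#' @export
duplex_metrics <- function(candidate, fold, alignments) {
  n <- nchar(candidate$seq)
  m1 <- candidate$mature_offset + 1L          # 1-based window coords
  m2 <- candidate$mature_offset + candidate$mature_len
  invalid <- function(reason)
    structure(list(valid = FALSE, reason = reason,
                   mature_count = 0L, star_count = 0L, loop_count = 0L,
                   overhang3 = NA_real_, overhang3_mature = NA_real_,
                   overhang3_star = NA_real_,
                   five_prime_consistency = NA_real_,
                   stem_mismatches = NA_integer_,
                   mature_paired_fraction = 0),
              class = "hairpin_metrics")
  # read coordinates in window space (1-based, 5'->3' of the window strand)
  win_reads <- NULL
  if (nrow(alignments) > 0) {
    al <- alignments[alignments$contig == candidate$contig &
                       alignments$strand == candidate$strand, , drop = FALSE]
    if (nrow(al) > 0) {
      if (candidate$strand == "+") {
        w1 <- al$start - candidate$start + 1L
        w2 <- al$end - candidate$start
      } else {
        w1 <- candidate$end - al$end + 1L
        w2 <- candidate$end - al$start
      }
      sel <- w2 >= 1 & w1 <= n     # reads overlapping the window
      win_reads <- data.frame(w1 = w1[sel], w2 = w2[sel])
    }
  }

  # read classification is purely positional: mature = majority overlap with
  # the modal read; the star arm, when sequenced, is the modal span of the
  # remaining in-window reads clear of the mature arm
  mature_count <- 0L; star_count <- 0L; loop_count <- 0L
  consistency <- NA_real_
  star_read_start <- NA_integer_; star_read_end <- NA_integer_
  if (!is.null(win_reads) && nrow(win_reads) > 0) {
    ov <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1) + 1)
    o_mat <- ov(win_reads$w1, win_reads$w2, m1, m2)
    frac_mat <- o_mat / (win_reads$w2 - win_reads$w1 + 1)
    is_mat <- frac_mat >= 0.5
    rest <- win_reads[!is_mat & o_mat == 0, , drop = FALSE]
    mature_count <- sum(is_mat)
    if (mature_count > 0)
      consistency <- sum(win_reads$w1[is_mat] == m1) / mature_count
    if (nrow(rest) > 0) {
      s1 <- as.integer(names(which.max(table(rest$w1))))
      cluster <- rest[abs(rest$w1 - s1) <= 3, , drop = FALSE]
      star_read_start <- s1
      star_read_end <- as.integer(names(which.max(table(cluster$w2))))
      is_star <- abs(rest$w1 - star_read_start) <= 3
      star_count <- sum(is_star)
      loop_count <- nrow(rest) - star_count
    }
    loop_count <- loop_count + sum(!is_mat & o_mat > 0)
  }

  # with read-defined arms, refold the read-delimited precursor: the duplex
  # geometry is then measured without unrelated flank structure
  partner <- fold$partner
  if (!is.na(star_read_end)) {
    t1 <- max(1L, min(m1, star_read_start))
    t2 <- min(n, max(m2, star_read_end))
    if (t2 - t1 + 1L >= 30 && m1 >= t1 && m2 <= t2) {
      sub <- substr(candidate$seq, t1, t2)
      refold <- nussinov_fold(sub)
      partner <- rep(0L, n)
      hit <- which(refold$partner > 0)
      partner[hit + t1 - 1L] <- refold$partner[hit] + t1 - 1L
    }
  }
  dp <- duplex_pairs(partner, m1, m2, candidate$mature_len)
  if (is.null(dp) && !identical(partner, fold$partner))
    dp <- duplex_pairs(fold$partner, m1, m2, candidate$mature_len)
  if (is.null(dp)) return(invalid("no duplex pairing"))

  # 3' protrusions: a strand's 3' end is its highest window coordinate
  overhang_mature <- m2 - max(dp$mature)
  star_end <- if (!is.na(star_read_end)) star_read_end else max(dp$partners)
  overhang_star <- star_end - max(dp$partners)
  if (overhang_star < 0 || overhang_star > 10) overhang_star <- NA_real_

  duplex_n <- length(dp$mature)
  structure(list(
    valid = TRUE,
    star_span = c(min(dp$partners), max(dp$partners)),
    mature_count = mature_count, star_count = star_count,
    loop_count = loop_count,
    overhang3_mature = as.numeric(overhang_mature),
    overhang3_star = as.numeric(overhang_star),
    overhang3 = max(c(overhang_mature, overhang_star), na.rm = TRUE),
    five_prime_consistency = consistency,
    stem_mismatches = as.integer(candidate$mature_len - duplex_n),
    mature_paired_fraction = duplex_n / candidate$mature_len),
    class = "hairpin_metrics")
}

#' Plausibility score of a candidate
#'
#' `log2(1 + mature_count) + 3 * [star reads present] +
#' 5 * mature_paired_fraction` - a documented, deterministic stand-in for a
#' probabilistic discovery score; the default passing threshold is 10.
#'
#' @param metrics a `hairpin_metrics` object.
#' @return numeric score.
#' @export
score_candidate <- function(metrics) {
  log2(1 + metrics$mature_count) + 3 * (metrics$star_count >= 1) +
    5 * metrics$mature_paired_fraction
}

#' Classification thresholds for bona fide miRNA calling
#'
#' @param min_score minimum plausibility score (default 10).
#' @param overhang required 3' overhang in nt (default 2).
#' @param overhang_tol tolerance on the overhang (default 0).
#' @param min_consistency minimum 5'-end consistency (default 0.8).
#' @param max_stem_mismatch maximum unpaired mature bases in the stem
#'   (default 4).
#' @param min_paired_fraction minimum fraction of mature bases paired into
#'   the star arm (default 0.6).
#' @param rescue_max_overhang maximum overhang rescuable by conservation
#'   (default 3).
#' @return list of thresholds.
#' @export
bona_fide_thresholds <- function(min_score = 10, overhang = 2,
                                 overhang_tol = 0, min_consistency = 0.8,
                                 max_stem_mismatch = 4,
                                 min_paired_fraction = 0.6,
                                 rescue_max_overhang = 3) {
  as.list(environment())
}

#' Classify candidates as bona fide miRNAs
#'
#' A candidate passes when its score, overhang, 5'-end consistency, stem
#' mismatches and paired fraction all clear the thresholds. A candidate whose
#' only failure is the overhang criterion, with an overhang of at most
#' `rescue_max_overhang` nt and at least one conservation hit, is rescued
#' (`rescued_by_conservation = TRUE`) - mirroring the treatment of a
#' conserved precursor with a 3-bp 3' overhang.
#'
#' @param candidate_ids character vector of candidate ids.
#' @param metrics_list list of `hairpin_metrics`, parallel to
#'   `candidate_ids`.
#' @param known_hits list (parallel) of conservation-hit data.frames from
#'   [match_known()]; may contain empty data.frames.
#' @param thresholds a [bona_fide_thresholds()] list.
#' @return data.frame of verdicts: `candidate`, `score`, the metric columns,
#'   `failed` (semicolon-joined criteria), `rescued_by_conservation`,
#'   `passed`.
#' @export
classify <- function(candidate_ids, metrics_list, known_hits = NULL,
                     thresholds = bona_fide_thresholds()) {
  th <- thresholds
  rows <- lapply(seq_along(candidate_ids), function(i) {
    m <- metrics_list[[i]]
    score <- score_candidate(m)
    failed <- character(0)
    if (!isTRUE(m$valid)) failed <- c(failed, "fold")
    if (score < th$min_score) failed <- c(failed, "score")
    ov_ok <- !is.na(m$overhang3) &&
      abs(m$overhang3 - th$overhang) <= th$overhang_tol
    if (!ov_ok) failed <- c(failed, "overhang")
    if (is.na(m$five_prime_consistency) ||
        m$five_prime_consistency < th$min_consistency)
      failed <- c(failed, "consistency")
    if (is.na(m$stem_mismatches) ||
        m$stem_mismatches > th$max_stem_mismatch)
      failed <- c(failed, "stem_mismatches")
    if (m$mature_paired_fraction < th$min_paired_fraction)
      failed <- c(failed, "paired_fraction")
    n_hits <- if (is.null(known_hits)) 0L else nrow(known_hits[[i]])
    rescued <- identical(failed, "overhang") &&
      !is.na(m$overhang3) && m$overhang3 <= th$rescue_max_overhang &&
      n_hits >= 1
    passed <- length(failed) == 0 || rescued
    data.frame(candidate = candidate_ids[i], score = score,
               mature_count = m$mature_count, star_count = m$star_count,
               loop_count = m$loop_count, overhang3 = m$overhang3,
               five_prime_consistency = m$five_prime_consistency,
               stem_mismatches = m$stem_mismatches,
               mature_paired_fraction = m$mature_paired_fraction,
               conservation_hits = n_hits,
               failed = paste(failed, collapse = ";"),
               rescued_by_conservation = rescued, passed = passed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Discover miRNAs from cleaned reads and a genome
#'
#' Chains mapping, stack calling, precursor excision, folding, metrics and
#' classification; the better-scoring of the two excised windows represents
#' each stack.
#'
#' @param reads cleaned reads.
#' @param genome genome records.
#' @param known optional known-miRNA reference records for conservation
#'   rescue and naming.
#' @param thresholds a [bona_fide_thresholds()] list.
#' @param min_len,max_loci mapping parameters (see [map_reads()]).
#' @param min_count,merge_gap stack parameters (see [call_stacks()]).
#' @param flank excision flank (see [excise_precursors()]).
#' @return list with `alignments`, `stacks`, `candidates` (chosen window per
#'   stack, incl. mature sequence), `metrics`, `verdicts`, `hits`.
#' @export
discover_mirnas <- function(reads, genome, known = NULL,
                            thresholds = bona_fide_thresholds(),
                            min_len = 18, max_loci = 5,
                            min_count = 10, merge_gap = 2, flank = 70) {
  aln <- map_reads(reads, genome, min_len = min_len, max_loci = max_loci)
  stacks <- call_stacks(aln, min_count = min_count, merge_gap = merge_gap)
  candidates <- list(); metrics <- list(); hits <- list()
  mature_seqs <- character(0)
  for (si in seq_len(nrow(stacks))) {
    st <- stacks[si, ]
    wins <- excise_precursors(st, genome, flank = flank)
    if (is.null(wins)) next
    best <- NULL
    for (wi in seq_len(nrow(wins))) {
      cand <- wins[wi, ]
      fold <- fold_hairpin(cand$seq)
      m <- duplex_metrics(cand, fold, aln)
      s <- score_candidate(m)
      if (is.null(best) || s > best$score)
        best <- list(cand = cand, fold = fold, metrics = m, score = s)
    }
    if (is.null(best)) next
    id <- sprintf("cand-%s-%d-%s", st$contig, st$modal5, st$strand)
    mature <- substr(best$cand$seq, best$cand$mature_offset + 1,
                     best$cand$mature_offset + best$cand$mature_len)
    candidates[[length(candidates) + 1]] <-
      cbind(best$cand, candidate = id, mature_seq = mature,
            structure = best$fold$structure, stringsAsFactors = FALSE)
    metrics[[length(metrics) + 1]] <- best$metrics
    hits[[length(hits) + 1]] <-
      if (is.null(known)) empty_hits() else match_known(mature, known)
    mature_seqs <- c(mature_seqs, mature)
  }
  cand_df <- if (length(candidates)) do.call(rbind, candidates) else NULL
  verdicts <- if (length(candidates))
    classify(cand_df$candidate, metrics, hits, thresholds) else NULL
  list(alignments = aln, stacks = stacks, candidates = cand_df,
       metrics = metrics, verdicts = verdicts, hits = hits)
}
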