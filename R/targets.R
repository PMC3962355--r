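# miRNA target prediction by site accessibility.
#
# 3' UTRs are the transcript suffix downstream of the longest forward-frame
# ORF; UTRs under 100 bp are discarded. For each seed match the score is
# ddG = dG_duplex + open_cost: the duplex energy of the miRNA bound to the
# site (simplified per-pair model, G:C/A:U/G:U = -3/-2/-1 kcal/mol) plus the
# cost (>= 0) of opening the site's local secondary structure, computed as
# the difference between the unconstrained and site-unpaired folds of the
# +/- `window` context. Sites with ddG <= -10 kcal/mol are retained by
# default.

#' Find the longest open reading frame
#'
#' Scans the three forward frames for ATG-initiated spans terminated by a
#' stop codon (span includes the stop) or by the transcript end; returns the
#' longest, ties broken by the smaller start coordinate.
#'
#' @param seq transcript sequence (DNA).
#' @return list(`frame`, `start`, `end`, `length`) with 0-based half-open
#'   coordinates, or `NULL` when no ATG exists.
#' @export
longest_orf <- function(seq) {
  seq <- norm_dna(seq)
  L <- nchar(seq)
  if (L < 3) return(NULL)
  best <- NULL
  for (frame in 0:2) {
    starts <- seq(frame + 1, L - 2, by = 3)
    if (length(starts) == 0) next
    codons <- substring(seq, starts, starts + 2)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    stop_idx <- which(is_stop)
    for (ai in which(is_atg)) {
      nxt <- stop_idx[stop_idx >= ai]
      if (length(nxt)) {
        s0 <- starts[ai] - 1L
        e0 <- starts[nxt[1]] + 2L
      } else {
        s0 <- starts[ai] - 1L
        e0 <- L                      # end-truncated ORF
      }
      len <- e0 - s0
      if (is.null(best) || len > best$length ||
          (len == best$length && s0 < best$start))
        best <- list(frame = frame, start = s0, end = e0, length = len)
    }
  }
  best
}

#' Extract the 3' UTR downstream of an ORF
#'
#' @param seq transcript sequence.
#' @param orf result of [longest_orf()] (may be `NULL`).
#' @param min_len minimum UTR length retained (default 100).
#' @return the UTR sequence, or `NULL` when absent or shorter than
#'   `min_len`.
#' @export
extract_utr3 <- function(seq, orf, min_len = 100) {
  if (is.null(orf)) return(NULL)
  utr <- substr(norm_dna(seq), orf$end + 1, nchar(seq))
  if (nchar(utr) < min_len) return(NULL)
  utr
}

#' Seed-match positions of a miRNA in a UTR
#'
#' Reports every UTR position holding the reverse complement of the miRNA
#' seed (positions `seed_start .. seed_start + seed_len - 1`, 1-based from
#' the miRNA 5' end; default the 7-mer at positions 2-8). Watson-Crick
#' matches only unless `allow_gu`.
#'
#' @param mature mature miRNA sequence.
#' @param utr UTR sequence.
#' @param seed_len seed length (6, 7 or 8; default 7).
#' @param seed_start first seed position on the miRNA (default 2).
#' @param allow_gu allow G:U wobble in the seed match (default FALSE).
#' @return integer vector of 1-based UTR start positions of the site.
#' @export
seed_matches <- function(mature, utr, seed_len = 7, seed_start = 2,
                         allow_gu = FALSE) {
  mature <- norm_dna(mature); utr <- norm_dna(utr)
  if (nchar(mature) < seed_start + seed_len - 1)
    stop("mature miRNA shorter than the seed span", call. = FALSE)
  seed <- substr(mature, seed_start, seed_start + seed_len - 1)
  if (!allow_gu) {
    # lookahead keeps overlapping occurrences
    pat <- paste0("(?=", revcomp(seed), ")")
    hits <- gregexpr(pat, utr, perl = TRUE)[[1]]
    if (hits[1] == -1) return(integer(0))
    return(as.integer(hits))
  }
  # G:U-tolerant scan: utr[s + seed_len - k] must pair mature[seed_start+k-1]
  sv <- rev(seq_chars(seed))   # site 5'->3' pairs seed 3'->5'
  uv <- seq_chars(utr)
  n <- nchar(utr)
  out <- integer(0)
  for (s in seq_len(n - seed_len + 1)) {
    if (all(can_pair(sv, uv[s:(s + seed_len - 1)], allow_gu = TRUE)))
      out <- c(out, s)
  }
  out
}

#' Duplex binding energy of a miRNA at a site
#'
#' Starts from the seed pairing and extends outward base by base on both
#' sides while Watson-Crick or G:U pairs form; the first mismatch stops the
#' extension on its side. Energies are the simplified per-pair magnitudes
#' (G:C 3, A:U 2, G:U 1), returned as a negative kcal/mol value.
#'
#' @param mature mature miRNA sequence.
#' @param utr UTR sequence.
#' @param site 1-based UTR position from [seed_matches()].
#' @param seed_len,seed_start seed definition (as in [seed_matches()]).
#' @return list(`dg` (kcal/mol, <= 0), `site_start`, `site_end`: the UTR
#'   span covered by the paired region).
#' @export
duplex_dG <- function(mature, utr, site, seed_len = 7, seed_start = 2) {
  mature <- norm_dna(mature); utr <- norm_dna(utr)
  mv <- seq_chars(mature); uv <- seq_chars(utr)
  lm <- length(mv); lu <- length(uv)
  # miRNA position p (1-based) pairs UTR position site + seed_len - 1 -
  # (p - seed_start) ; antiparallel geometry
  upos <- function(p) site + seed_len - 1L - (p - seed_start)
  e <- 0
  lo_u <- site; hi_u <- site + seed_len - 1L
  for (p in seed_start:(seed_start + seed_len - 1L))
    e <- e + pair_energy_abs(mv[p], uv[upos(p)])
  # extend towards the miRNA 3' end (UTR 5' direction)
  p <- seed_start + seed_len
  while (p <= lm && upos(p) >= 1) {
    w <- pair_energy_abs(mv[p], uv[upos(p)])
    if (w == 0) break
    e <- e + w
    lo_u <- upos(p)
    p <- p + 1L
  }
  # extend towards the miRNA 5' end (UTR 3' direction)
  p <- seed_start - 1L
  while (p >= 1 && upos(p) <= lu) {
    w <- pair_energy_abs(mv[p], uv[upos(p)])
    if (w == 0) break
    e <- e + w
    hi_u <- upos(p)
    p <- p - 1L
  }
  list(dg = -e, site_start = lo_u, site_end = hi_u)
}

#' Cost of opening a target site's secondary structure
#'
#' Folds the +/- `window` nt context around the site twice - unconstrained,
#' and with the site bases forced unpaired - and returns the energy
#' difference in kcal/mol (>= 0 by construction).
#'
#' @param utr UTR sequence.
#' @param site_start,site_end 1-based UTR span of the site.
#' @param window context size on each side (default 70; clipped at UTR
#'   ends).
#' @return opening cost in kcal/mol (>= 0).
#' @export
open_cost <- function(utr, site_start, site_end, window = 70) {
  utr <- norm_dna(utr)
  L <- nchar(utr)
  a <- max(1L, site_start - window)
  b <- min(L, site_end + window)
  ctx <- substr(utr, a, b)
  forbidden <- rep(FALSE, b - a + 1L)
  forbidden[(site_start - a + 1L):(site_end - a + 1L)] <- TRUE
  free <- nussinov_fold(ctx)
  constrained <- nussinov_fold(ctx, forbidden = forbidden)
  as.numeric(free$score - constrained$score)
}

#' Predict miRNA target sites on a set of 3' UTRs
#'
#' For every (miRNA, UTR, seed match): `ddG = dG_duplex + open_cost`;
#' sites with `ddG <= cutoff` are retained. Output is ordered by ddG then
#' coordinates, with the best site per (miRNA, transcript) flagged.
#'
#' @param matures data.frame of mature miRNAs (`id`, `seq`).
#' @param utrs data.frame of UTRs (`id`, `seq`), e.g. built with
#'   [longest_orf()] + [extract_utr3()].
#' @param cutoff retention threshold in kcal/mol (default -10).
#' @param seed_len,seed_start,allow_gu seed definition.
#' @param window opening-cost context (default 70).
#' @return data.frame: `mirna`, `transcript`, `utr_start`, `utr_end`,
#'   `seed_class`, `dg_duplex`, `open_cost`, `ddg`, `retained`, `best`.
#' @export
predict_targets <- function(matures, utrs, cutoff = -10, seed_len = 7,
                            seed_start = 2, allow_gu = FALSE, window = 70) {
  rows <- list()
  seed_class <- sprintf("%dmer", seed_len)
  for (mi in seq_len(nrow(matures))) {
    m <- norm_dna(matures$seq[mi])
    for (ui in seq_len(nrow(utrs))) {
      u <- norm_dna(utrs$seq[ui])
      for (s in seed_matches(m, u, seed_len, seed_start, allow_gu)) {
        dup <- duplex_dG(m, u, s, seed_len, seed_start)
        oc <- open_cost(u, dup$site_start, dup$site_end, window)
        rows[[length(rows) + 1]] <- data.frame(
          mirna = matures$id[mi], transcript = utrs$id[ui],
          utr_start = dup$site_start, utr_end = dup$site_end,
          seed_class = seed_class, dg_duplex = dup$dg, open_cost = oc,
          ddg = dup$dg + oc, retained = dup$dg + oc <= cutoff,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(mirna = character(0), transcript = character(0),
                      utr_start = integer(0), utr_end = integer(0),
                      seed_class = character(0), dg_duplex = numeric(0),
                      open_cost = numeric(0), ddg = numeric(0),
                      retained = logical(0), best = logical(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$ddg, out$mirna, out$transcript, out$utr_start), ,
             drop = FALSE]
  key <- paste(out$mirna, out$transcript)
  out$best <- !duplicated(key)
  rownames(out) <- NULL
  out
}

#' Extract all qualifying 3' UTRs from transcripts
#'
#' @param transcripts data.frame of transcript records.
#' @param min_len minimum UTR length (default 100).
#' @return data.frame (`id`, `seq`) of UTRs passing the length filter.
#' @export
extract_all_utrs <- function(transcripts, min_len = 100) {
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    orf <- longest_orf(transcripts$seq[i])
    utr <- extract_utr3(transcripts$seq[i], orf, min_len = min_len)
    if (!is.null(utr))
      rows[[length(rows) + 1]] <- data.frame(id = transcripts$id[i],
                                             seq = utr,
                                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(id = character(0), seq = character(0)))
  do.call(rbind, rows)
}
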