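# Conservation matching of predicted mature miRNAs against a known-miRNA
# reference (miRBase-style ids such as "nve-miR-2023"). Queries are ~22 nt,
# so an exhaustive end-gap-free offset scan is exact and replaces heuristic
# seeded alignment; no gaps (known cnidarian family alignments are ungapped).

empty_hits <- function() {
  data.frame(query = character(0), subject = character(0),
             offset = integer(0), overlap = integer(0),
             mismatches = integer(0), family = character(0),
             stringsAsFactors = FALSE)
}

# family name from a miRBase-style id: "nve-miR-2023" -> "miR-2023"
mirna_family <- function(id) {
  vapply(id, function(x) {
    m <- regmatches(x, regexpr("(miR|let|lin|bantam)-[0-9A-Za-z.]+", x))
    if (length(m) && nzchar(m)) m else x
  }, character(1), USE.NAMES = FALSE)
}

#' Match a mature miRNA against known miRNA sequences
#'
#' For each reference subject the best end-gap-free alignment is sought.
#' Mature-length subjects are scanned over offsets in
#' `[-max_offset, max_offset]`; longer (precursor) subjects additionally
#' slide the query along their full length. Overhanging bases are not
#' counted as mismatches but are limited to `max_offset` per end; hits with
#' at most `max_mismatch` mismatches over the overlap are returned, sorted
#' by mismatches then |offset|.
#'
#' @param query mature sequence (DNA or RNA; >= 18 nt).
#' @param reference data.frame of reference records ([read_fasta()]).
#' @param max_mismatch maximum mismatches in the overlap (default 3).
#' @param max_offset maximum end offset / query overhang in nt (default 3).
#' @return data.frame of hits: `query`, `subject`, `offset`, `overlap`,
#'   `mismatches`, `family`.
#' @export
match_known <- function(query, reference, max_mismatch = 3, max_offset = 3) {
  if (is.null(reference) || nrow(reference) == 0) return(empty_hits())
  q <- norm_dna(query)
  lq <- nchar(q)
  if (lq < 18) stop("query shorter than 18 nt", call. = FALSE)
  qv <- seq_chars(q)
  rows <- list()
  for (ri in seq_len(nrow(reference))) {
    s <- norm_dna(reference$seq[ri])
    ls <- nchar(s)
    sv <- seq_chars(s)
    # offset o: query position 1 aligns with subject position 1 + o
    offs <- (-max_offset):(ls - lq + max_offset)
    best <- NULL
    for (o in offs) {
      a <- max(1L, 1L + o); b <- min(ls, lq + o)    # subject overlap
      if (b - a + 1L < lq - max_offset) next        # query overhang too big
      qi <- (a - o):(b - o)
      mm <- sum(qv[qi] != sv[a:b])
      if (mm > max_mismatch) next
      cand <- list(offset = o, overlap = b - a + 1L, mm = mm)
      if (is.null(best) || mm < best$mm ||
          (mm == best$mm && abs(o) < abs(best$offset))) best <- cand
    }
    if (!is.null(best))
      rows[[length(rows) + 1]] <- data.frame(
        query = query, subject = reference$id[ri], offset = best$offset,
        overlap = best$overlap, mismatches = best$mm,
        family = mirna_family(reference$id[ri]), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits[order(hits$mismatches, abs(hits$offset)), , drop = FALSE]
}

#' Assign names to classified miRNAs
#'
#' Conserved passers are named `<prefix>-miR-<family>` after their best
#' conservation hit; novel passers are named `<prefix>-miR-temp-<rank>` in
#' order of descending plausibility score. Duplicate family assignments are
#' disambiguated with -1/-2 suffixes.
#'
#' @param verdicts data.frame from [classify()].
#' @param hits list of hit data.frames, parallel to `verdicts` rows.
#' @param prefix species prefix (default "spi").
#' @return data.frame: `candidate`, `name`, `conserved`, `score`.
#' @export
assign_names <- function(verdicts, hits, prefix = "spi") {
  if (is.null(verdicts) || nrow(verdicts) == 0)
    return(data.frame(candidate = character(0), name = character(0),
                      conserved = logical(0), score = numeric(0)))
  pass <- which(verdicts$passed)
  if (length(pass) == 0)
    return(data.frame(candidate = character(0), name = character(0),
                      conserved = logical(0), score = numeric(0)))
  conserved <- vapply(pass, function(i) nrow(hits[[i]]) > 0, logical(1))
  name <- character(length(pass))
  fam <- vapply(pass, function(i)
    if (nrow(hits[[i]]) > 0) hits[[i]]$family[1] else NA_character_,
    character(1))
  name[conserved] <- sub("^miR", paste0(prefix, "-miR"), fam[conserved])
  # novel passers ranked by descending score
  novel <- which(!conserved)
  rank <- order(-verdicts$score[pass][novel])
  name[novel[rank]] <- sprintf("%s-miR-temp-%d", prefix, seq_along(novel))
  # disambiguate duplicates
  dup <- names(which(table(name) > 1))
  for (d in dup) {
    idx <- which(name == d)
    name[idx] <- paste0(d, "-", seq_along(idx))
    message(sprintf("family %s assigned to %d precursors; suffixed", d,
                    length(idx)))
  }
  data.frame(candidate = verdicts$candidate[pass], name = name,
             conserved = conserved, score = verdicts$score[pass],
             stringsAsFactors = FALSE)
}
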