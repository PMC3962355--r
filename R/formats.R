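# On-disk formats: FASTA, FASTQ (Phred+33), OBO subset, TSV.
#
# The readers are strict by design: the pipeline's statistics are undefined on
# malformed input, so every contract violation is reported with its location
# rather than silently repaired. Quality encoding below '!' (Phred+64 data)
# fails loudly; only Phred+33 is supported.

fmt_error <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a FASTA file
#'
#' Multi-line sequences are concatenated; sequences are normalised to
#' upper-case DNA (U becomes T) while headers keep their case. `N` is allowed
#' (genome contigs may contain no-calls).
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `desc`, `seq`, one row per record,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) fmt_error("FASTA file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0 || all(grepl("^\\s*$", lines)))
    fmt_error("empty FASTA file: %s", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    fmt_error("%s: sequence line before first header (line 1)", path)
  rec <- cumsum(is_hdr)
  hdr <- sub("^>", "", lines[is_hdr])
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (any(id == "")) fmt_error("%s: empty record id", path)
  seqlines <- lines
  seqlines[is_hdr] <- ""
  bad <- grepl("[^ACGTUNacgtun]", seqlines)
  if (any(bad))
    fmt_error("%s: illegal sequence character at line %d", path,
              which(bad)[1])
  seqs <- vapply(split(seqlines, rec), paste, character(1), collapse = "")
  seqs <- unname(seqs)
  if (any(seqs == ""))
    fmt_error("%s: record '%s' has an empty sequence", path,
              id[which(seqs == "")[1]])
  data.frame(id = id, desc = desc, seq = norm_dna(seqs),
             stringsAsFactors = FALSE)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path path to a 4-line-record FASTQ file.
#' @return data.frame with columns `id`, `seq` (upper-case DNA) and `qual`
#'   (the raw Phred+33 quality string). Decode scores with [phred_scores()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) fmt_error("FASTQ file not found: %s", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0) fmt_error("empty FASTQ file: %s", path)
  if (n %% 4 != 0)
    fmt_error("%s: line count %d not divisible by 4", path, n)
  hdr <- lines[seq(1, n, by = 4)]
  seqs <- lines[seq(2, n, by = 4)]
  plus <- lines[seq(3, n, by = 4)]
  qual <- lines[seq(4, n, by = 4)]
  if (!all(startsWith(hdr, "@")))
    fmt_error("%s: record header missing '@' at line %d", path,
              (which(!startsWith(hdr, "@"))[1] - 1) * 4 + 1)
  if (!all(startsWith(plus, "+")))
    fmt_error("%s: separator line missing '+' at line %d", path,
              (which(!startsWith(plus, "+"))[1] - 1) * 4 + 3)
  if (any(nchar(seqs) != nchar(qual))) {
    i <- which(nchar(seqs) != nchar(qual))[1]
    fmt_error("%s: sequence/quality length mismatch in record %d", path, i)
  }
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad))
    fmt_error("%s: illegal read character at line %d", path,
              (which(bad)[1] - 1) * 4 + 2)
  qmin <- vapply(qual, function(q)
    if (nchar(q)) min(utf8ToInt(q)) else 33L, integer(1), USE.NAMES = FALSE)
  if (any(qmin < 33))
    fmt_error("%s: quality character below '!' in record %d (Phred+64 input?)",
              path, which(qmin < 33)[1])
  data.frame(id = sub("\\s.*$", "", sub("^@", "", hdr)),
             seq = toupper(seqs), qual = qual, stringsAsFactors = FALSE)
}

#' Decode a Phred+33 quality string
#'
#' @param qual a single quality string.
#' @return integer vector of Phred scores (`ord(char) - 33`).
#' @export
phred_scores <- function(qual) {
  if (nchar(qual) == 0) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' Encode Phred scores as a +33 quality string
#' @param q integer vector of Phred scores in 0..93.
#' @return a quality string.
#' @export
phred_encode <- function(q) {
  stopifnot(all(q >= 0), all(q <= 93))
  intToUtf8(as.integer(q) + 33L)
}

#' Write sequence records to FASTA or FASTQ
#'
#' Round-trips with [read_fasta()] / [read_fastq()] field for field.
#'
#' @param records data.frame with `id`, `seq` and (for fastq) `qual`;
#'   an optional `desc` column is emitted on FASTA headers.
#' @param path output path.
#' @param dialect `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, dialect = c("fasta", "fastq")) {
  dialect <- match.arg(dialect)
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (any(records$seq == "")) fmt_error("cannot write empty sequences")
  if (dialect == "fasta") {
    desc <- if ("desc" %in% names(records)) records$desc else ""
    hdr <- paste0(">", records$id, ifelse(desc == "", "", paste0(" ", desc)))
    writeLines(rbind(hdr, records$seq), path)
  } else {
    if (is.null(records$qual) || anyNA(records$qual))
      fmt_error("fastq dialect requires a qual column")
    if (any(nchar(records$qual) != nchar(records$seq)))
      fmt_error("fastq record with seq/qual length mismatch")
    writeLines(rbind(paste0("@", records$id), records$seq, "+",
                     records$qual), path)
  }
  invisible(path)
}

#' Parse an OBO-subset ontology file
#'
#' Understands `[Term]` stanzas with `id:`, `name:`, `is_a:` and
#' `is_obsolete:` tags. Obsolete terms are excluded (together with edges
#' pointing at them); an `is_a` reference to a genuinely unknown term is an
#' error, as is any `is_a` cycle.
#'
#' @param path path to an OBO file.
#' @return an `ontology_dag` object: list with `terms` (ids), `names`
#'   (named character), `parents` (named list of parent ids) and `roots`.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) fmt_error("OBO file not found: %s", path)
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) fmt_error("%s: no [Term] stanzas", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0)
  parents <- list(); obsolete <- character(0)
  for (s in seq_along(starts)) {
    block <- lines[(bounds[s] + 1):(bounds[s + 1] - 1)]
    block <- block[block != ""]
    block <- block[!startsWith(block, "[")]
    id <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE))
    if (length(id) != 1 || id == "")
      fmt_error("%s: [Term] stanza %d lacks an id", path, s)
    nm <- sub("^name:\\s*", "", grep("^name:", block, value = TRUE))
    isa <- sub("\\s*!.*$", "",
               sub("^is_a:\\s*", "", grep("^is_a:", block, value = TRUE)))
    obs <- grep("^is_obsolete:\\s*true", block, value = TRUE)
    if (length(obs)) { obsolete <- c(obsolete, id); next }
    ids <- c(ids, id)
    nms[id] <- if (length(nm)) nm[1] else id
    parents[[id]] <- isa
  }
  # drop edges to obsolete terms; unknown endpoints are an error
  parents <- lapply(parents, function(p) setdiff(p, obsolete))
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown))
    fmt_error("%s: is_a reference to unknown term %s", path, unknown[1])
  dag <- structure(list(terms = ids, names = nms, parents = parents,
                        roots = ids[vapply(parents[ids], length,
                                           integer(1)) == 0]),
                   class = "ontology_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc))
    fmt_error("%s: is_a cycle: %s", path, paste(cyc, collapse = " -> "))
  dag
}

# DFS cycle detection; returns one cycle (as an id path) or NULL
find_cycle <- function(dag) {
  colour <- setNames(rep(0L, length(dag$terms)), dag$terms)
  path <- character(0)
  found <- NULL
  visit <- function(t) {
    if (!is.null(found)) return()
    colour[[t]] <<- 1L
    path <<- c(path, t)
    for (p in dag$parents[[t]]) {
      if (colour[[p]] == 1L) {
        i <- which(path == p)
        found <<- c(path[i:length(path)], p)
        return()
      }
      if (colour[[p]] == 0L) visit(p)
      if (!is.null(found)) return()
    }
    colour[[t]] <<- 2L
    path <<- path[-length(path)]
  }
  for (t in dag$terms) if (colour[[t]] == 0L) visit(t)
  found
}

#' Ancestor set of an ontology term
#'
#' @param dag an `ontology_dag` from [parse_obo()].
#' @param term a term id.
#' @return character vector of all (transitive) ancestors, excluding `term`.
#' @export
ancestors <- function(dag, term) {
  if (!term %in% dag$terms) fmt_error("unknown term: %s", term)
  out <- character(0)
  queue <- dag$parents[[term]]
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    if (t %in% out) next
    out <- c(out, t)
    queue <- c(queue, dag$parents[[t]])
  }
  out
}

# term depth: longest is_a path from a root (roots have depth 0); memoised
term_depths <- function(dag) {
  depth <- setNames(rep(NA_integer_, length(dag$terms)), dag$terms)
  get_depth <- function(t) {
    if (!is.na(depth[[t]])) return(depth[[t]])
    p <- dag$parents[[t]]
    d <- if (length(p) == 0) 0L else
      max(vapply(p, get_depth, integer(1))) + 1L
    depth[[t]] <<- d
    d
  }
  for (t in dag$terms) get_depth(t)
  depth
}
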