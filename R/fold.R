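# RNA secondary structure via a weighted Nussinov dynamic program.
#
# The bona fide miRNA filters depend on pairing topology (which bases of the
# mature arm pair into the star arm, and where the duplex ends), not on
# absolute free energies, so a maximum-weight pairing model with
# G:C/A:U/G:U = 3/2/1 and a minimum loop of 3 nt is used in place of a full
# nearest-neighbour thermodynamic model. The same engine, with per-position
# unpaired constraints, provides the opening-cost term of target-site
# accessibility.

#' Fold a sequence with the weighted Nussinov engine
#'
#' @param seq a DNA/RNA sequence (internally treated as DNA; T and U are
#'   equivalent).
#' @param forbidden optional logical vector, one per base; `TRUE` positions
#'   are constrained to remain unpaired.
#' @return list with `structure` (dot-bracket), `score` (total pair weight,
#'   G:C = 3, A:U = 2, G:U = 1) and `partner` (1-based partner index per
#'   position, 0 if unpaired).
#' @export
nussinov_fold <- function(seq, forbidden = NULL) {
  seq <- norm_dna(seq)
  n <- nchar(seq)
  if (is.null(forbidden)) forbidden <- rep(FALSE, n)
  if (length(forbidden) != n)
    stop("forbidden mask must have one entry per base", call. = FALSE)
  .nussinov_fold_cpp(seq, forbidden)
}

#' Fold a candidate pre-miRNA hairpin
#'
#' Input length is restricted to the plausible precursor range (30-150 nt).
#'
#' @param seq precursor window sequence.
#' @return as [nussinov_fold()].
#' @export
fold_hairpin <- function(seq) {
  n <- nchar(seq)
  if (n < 30 || n > 150)
    stop(sprintf("hairpin window length %d outside 30-150 nt", n),
         call. = FALSE)
  nussinov_fold(seq)
}
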