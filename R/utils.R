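# Shared sequence helpers. Internal alphabet is upper-case DNA; RNA input
# (u/U) is converted on read, and mature miRNAs are rendered back to
# lower-case RNA only at output time.

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# normalise a sequence to upper-case DNA (U -> T); no validation here
norm_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Render DNA as lower-case RNA
#'
#' Output dialect used for mature/star miRNA sequences (t -> u, lower case),
#' matching the convention of miRNA registries.
#'
#' @param x character vector of DNA sequences.
#' @return character vector in lower-case RNA.
#' @export
as_rna_lower <- function(x) {
  chartr("t", "u", tolower(x))
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# TRUE where bases a and b can pair (Watson-Crick or G:U wobble), DNA alphabet
can_pair <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (!allow_gu) return(wc)
  wc | (a == "G" & b == "T") | (a == "T" & b == "G")
}

# per-pair energy magnitude in kcal/mol under the simplified model
# (G:C = 3, A:U = 2, G:U = 1); 0 for non-pairs
pair_energy_abs <- function(a, b) {
  e <- numeric(length(a))
  gc <- (a == "G" & b == "C") | (a == "C" & b == "G")
  au <- (a == "A" & b == "T") | (a == "T" & b == "A")
  gu <- (a == "G" & b == "T") | (a == "T" & b == "G")
  e[gu] <- 1
  e[au] <- 2
  e[gc] <- 3
  e
}

# deterministic random DNA
random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# a base guaranteed not to pair (WC or G:U) with base m
nonpairing_base <- function(m) {
  switch(m, A = "C", C = "C", G = "A", T = "C", "C")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
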