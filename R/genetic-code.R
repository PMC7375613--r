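#' The standard genetic code on RNA codons
#'
#' Returns the standard genetic code as a named character vector mapping all
#' 64 RNA trinucleotides to one-letter amino-acid symbols, with `"*"` for the
#' three stop codons. The table is derived from [Biostrings::GENETIC_CODE]
#' with `T` transliterated to `U`.
#'
#' @return Named character vector of length 64; names are RNA codons.
#' @export
#' @examples
#' genetic_code()[["AUG"]]  # "M"
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("T", "U", names(gc))
  gc[order(names(gc))]
}

#' Sense and stop codons
#'
#' @return `sense_codons()`: the 61 sense RNA codons in lexicographic order.
#'   `stop_codons()`: the 3 stop codons.
#' @export
sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

#' @rdname sense_codons
#' @export
stop_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc == "*"]
}

#' Synonymous codons of an amino acid
#'
#' @param aa One-letter amino-acid symbol.
#' @return Character vector of RNA codons encoding `aa`.
#' @export
synonymous_codons <- function(aa) {
  gc <- genetic_code()
  names(gc)[gc == aa]
}

#' Split a nucleotide string into codons
#'
#' Accepts DNA or RNA alphabet (case-insensitive); `T` is transliterated to
#' `U` so all downstream code works on RNA codons.
#'
#' @param x A single nucleotide string whose length is a multiple of 3, or an
#'   already-split character vector of codons (returned normalized).
#' @return Character vector of RNA codons.
#' @export
codons_of <- function(x) {
  if (length(x) == 1L && nchar(x) > 3L) {
    if (nchar(x) %% 3L != 0L)
      stop("sequence length ", nchar(x), " is not a multiple of 3")
    x <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  }
  x <- chartr("Tt", "Uu", toupper(x))
  bad <- setdiff(unique(x), names(genetic_code()))
  if (length(bad))
    stop("invalid codon(s): ", paste(bad, collapse = ", "))
  x
}

#' Translate a codon vector
#'
#' @param codons Character vector of codons (DNA or RNA alphabet).
#' @return Single amino-acid string; stops translate to `"*"`.
#' @export
translate_codons <- function(codons) {
  paste(genetic_code()[codons_of(codons)], collapse = "")
}

#' Strip a terminal stop codon, if present
#'
#' @param codons Character vector of codons.
#' @return The codon vector without its trailing stop codon.
#' @export
strip_stop <- function(codons) {
  codons <- codons_of(codons)
  n <- length(codons)
  if (n > 0L && codons[n] %in% stop_codons()) codons <- codons[-n]
  codons
}

# Internal: map codons to 1..61 indices into sense_codons(); errors on stops.
codon_index <- function(codons, what = "ORF") {
  idx <- match(codons_of(codons), sense_codons())
  if (anyNA(idx))
    stop(what, " contains stop or invalid codon(s): ",
         paste(unique(codons[is.na(idx)]), collapse = ", "))
  idx
}
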