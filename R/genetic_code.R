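#' The standard genetic code and synonymous codon sets
#'
#' Codons are three-letter DNA strings over \{A, C, G, T\}; RNA input (U) is
#' normalized to T on read. The standard code has 64 codons, 3 stops
#' (TAA, TAG, TGA) and 61 sense codons whose synonymous sets (codons sharing
#' an amino acid) partition them.
#'
#' @return an object of class `genetic_code`: a list with `codons` (the 64
#'   codons), `aa` (named character, amino-acid one-letter symbol or `"*"`
#'   for stop), `stops`, `sense`, and `synonyms` (named list mapping each
#'   sense codon to its synonymous set, input included).
#' @export
#' @examples
#' code <- standard_genetic_code()
#' length(code$codons)         # 64
#' synonymous_codons("GCT", code)
standard_genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  # amino acids in TCAG nested order (standard code table order)
  aa_str <- paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG")
  aa <- strsplit(aa_str, "")[[1]]
  names(aa) <- codons
  sense <- codons[aa != "*"]
  syn <- split(sense, aa[sense])
  synonyms <- stats::setNames(lapply(sense, function(cd) syn[[aa[[cd]]]]), sense)
  structure(list(
    codons = codons, aa = aa,
    stops = codons[aa == "*"], sense = sense,
    synonyms = synonyms
  ), class = "genetic_code")
}

#' Normalize a codon string to DNA upper case
#'
#' @param codon character vector of 3-letter codons (RNA or DNA, any case).
#' @return character vector of DNA codons.
#' @export
normalize_codon <- function(codon) {
  x <- chartr("u", "T", chartr("U", "T", toupper(codon)))
  bad <- nchar(x) != 3 | grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  x
}

#' Synonymous codons of a sense codon
#'
#' @param codon a single sense codon (DNA or RNA spelling).
#' @param code a `genetic_code`, by default the standard code.
#' @return character vector of all codons encoding the same amino acid,
#'   including the input.
#' @export
synonymous_codons <- function(codon, code = standard_genetic_code()) {
  cd <- normalize_codon(codon)
  stopifnot(length(cd) == 1)
  if (cd %in% code$stops) {
    stop("codon ", cd, " is a stop codon; stop codons have no synonymous set")
  }
  if (!cd %in% code$sense) stop("codon ", cd, " is not in the genetic code")
  code$synonyms[[cd]]
}

.base_bits <- c(A = 0L, C = 1L, G = 2L, T = 3L)

#' 6-bit codon encoding
#'
#' Bijective encoding of a codon into `[0, 64)` using 2 bits per nucleotide
#' with the fixed mapping A=0, C=1, G=2, T=3; the first nucleotide occupies
#' the high bits. `decode_codon` is the inverse.
#'
#' @param codon character vector of codons.
#' @return integer vector in `[0, 64)`.
#' @export
encode_codon <- function(codon) {
  x <- normalize_codon(codon)
  m <- matrix(.base_bits[unlist(strsplit(x, ""))], nrow = 3)
  as.integer(m[1, ] * 16L + m[2, ] * 4L + m[3, ])
}

#' @rdname encode_codon
#' @param value integer vector in `[0, 64)`.
#' @export
decode_codon <- function(value) {
  stopifnot(all(value >= 0 & value < 64))
  b <- names(.base_bits)
  v <- as.integer(value)
  paste0(b[v %/% 16L + 1L], b[(v %/% 4L) %% 4L + 1L], b[v %% 4L + 1L])
}
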