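# Shared alphabet handling and numeric helpers.

# RNA alphabet with IUPAC degeneracy. Canonical bases come first so that
# codes 1:4 index emission vectors directly.
RNA_BASES <- c("A", "C", "G", "U")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

IUPAC_CODES <- names(IUPAC_SETS)

# Large negative sentinel standing in for log(0); keeps DP arithmetic total.
NEG_INF_SCORE <- -1e30

#' Normalize a nucleotide string to uppercase RNA
#'
#' DNA thymine is converted to uracil and lowercase letters are raised to
#' uppercase. Gap characters are left untouched.
#'
#' @param x character vector of sequence strings.
#' @return character vector of the same length over the RNA alphabet.
#' @keywords internal
normalize_rna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

#' Encode an RNA string as integer codes
#'
#' Canonical bases map to 1:4, IUPAC degeneracy codes to 5:15. Used at the
#' boundary between R objects and the C++ scoring kernels.
#'
#' @param seq a single sequence string (no gaps).
#' @return integer vector of codes in 1:15.
#' @keywords internal
encode_seq <- function(seq) {
  if (nchar(seq) == 0L) return(integer(0))
  chars <- strsplit(normalize_rna(seq), "", fixed = TRUE)[[1]]
  codes <- match(chars, IUPAC_CODES)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop("illegal sequence character '", chars[bad], "' at position ", bad)
  }
  codes
}

decode_seq <- function(codes) paste(IUPAC_CODES[codes], collapse = "")

#' Reverse complement of an RNA string
#'
#' IUPAC degeneracy codes are complemented set-wise (e.g. R -> Y).
#'
#' @param seq a single RNA string.
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) {
  comp <- c(A = "U", C = "G", G = "C", U = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  chars <- strsplit(normalize_rna(seq), "", fixed = TRUE)[[1]]
  paste(rev(unname(comp[chars])), collapse = "")
}

# log2-space sum of a vector, exact arithmetic (used by R-side oracles and
# small-scale statistics; the DP kernels have their own copies).
log2sumexp <- function(x) {
  x <- x[x > NEG_INF_SCORE / 2]
  if (length(x) == 0L) return(NEG_INF_SCORE)
  m <- max(x)
  m + log2(sum(2^(x - m)))
}

is_gap_char <- function(chars) {
  out <- chars %in% c("-", ".", "_", "~")
  if (is.matrix(chars)) dim(out) <- dim(chars)
  out
}

# Splits alignment rows into a character matrix (rows x columns).
aln_char_matrix <- function(rows) {
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
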