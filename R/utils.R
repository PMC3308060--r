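# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character strings (alphabet
#' ACGTN). Thin wrapper over Biostrings so the rest of the package can stay
#' in base character vectors.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse a plain string (used for quality strings of minus-strand reads).
str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

# Split equal-length strings into an n x width character matrix.
seq_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0))
  w <- unique(nchar(x))
  stopifnot(length(w) == 1L)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = w, byrow = TRUE)
}

# Collapse a character matrix back to one string per row.
matrix_seq <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Phred+33 encode/decode for quality strings.
qual_to_int <- function(q) lapply(q, function(s) utf8ToInt(s) - 33L)
int_to_qual <- function(q) vapply(q, function(v) intToUtf8(v + 33L), "",
                                  USE.NAMES = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
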