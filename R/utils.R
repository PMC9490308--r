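# Shared helpers: condition classes, label arithmetic, rounding.

stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "haplocode_validation_error")
}

stop_computation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "haplocode_computation_error")
}

#' Spreadsheet-style letter sequence
#'
#' Haplotype classes within a marker are lettered A, B, ..., Z, AA, AB, ...
#' in order of first appearance, so panels of any size get unique labels.
#'
#' @param n Number of letters needed.
#' @return Character vector of length `n`.
#' @keywords internal
class_letters <- function(n) {
  vapply(seq_len(n), function(i) {
    s <- character(0)
    while (i > 0) {
      r <- (i - 1L) %% 26L
      s <- c(LETTERS[r + 1L], s)
      i <- (i - 1L) %/% 26L
    }
    paste(s, collapse = "")
  }, character(1))
}

# Canonical haplotype label, e.g. marker_index 3 + letter "D" -> "H3^D".
haplotype_label <- function(marker_index, letter) {
  paste0("H", marker_index, "^", letter)
}

# Percentages are reported to one decimal place with half-up rounding,
# so 7/8 prints as 87.5 and 5/6 as 83.3.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# IUPAC nucleotide codes plus the alignment gap symbol.
IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# Uppercase and map RNA-style U to T; validation happens separately.
sanitize_sequence <- function(x) {
  chartr("U", "T", toupper(x))
}

# Position of the first non-IUPAC character, or 0L if the string is clean.
first_bad_char <- function(x) {
  pos <- regexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), x)
  as.integer(pos)
}

strip_gaps <- function(x) gsub("-", "", x, fixed = TRUE)

ungapped_length <- function(x) unname(nchar(strip_gaps(x)))
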