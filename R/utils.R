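# Internal sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors; `N` is
#' preserved. Thin wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of uppercase DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTTA"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out
}

# Complement of single bases without reversing (used to peek at the first
# base of a minus-strand insert without materialising it).
complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

# Pack sequences into a raw byte matrix (max width x n), padded with 0x20
# (space) beyond each sequence's end. Padding never equals a base byte, so
# padded positions always compare as mismatches and can be corrected by
# counting them.
seq_byte_matrix <- function(seqs) {
  widths <- nchar(seqs)
  w <- max(widths)
  padded <- formatC(seqs, width = -w, flag = "-")
  bytes <- charToRaw(paste(padded, collapse = ""))
  list(bytes = matrix(bytes, nrow = w), widths = widths)
}

assert_dna <- function(x, what, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- is.na(x) | !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf(
      "%s must be non-empty uppercase %s strings (%d offending entr%s)",
      what, if (allow_n) "A/C/G/T/N" else "A/C/G/T",
      sum(bad), if (sum(bad) == 1L) "y" else "ies"
    ), call. = FALSE)
  }
  invisible(x)
}

# Random DNA string(s) of the given lengths, drawn from the current RNG
# stream.
random_dna <- function(lengths) {
  if (length(lengths) == 0L) return(character(0))
  total <- sum(lengths)
  chars <- sample(DNA_BASES, total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  all <- paste(chars, collapse = "")
  substring(all, starts, ends)
}
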