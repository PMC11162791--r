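RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalise a nucleotide string to the RNA alphabet
#'
#' Folds to upper case and converts T to U (with a warning), the usual
#' tolerance for DNA-styled FASTA records. Any symbol outside {A,C,G,U}
#' after conversion is an error.
#'
#' @param x Character vector of sequences.
#' @param what Label used in messages.
#' @return Character vector over {A,C,G,U}.
#' @export
as_rna <- function(x, what = "sequence") {
  x <- toupper(x)
  if (any(grepl("T", x, fixed = TRUE))) {
    warning(sprintf("%s contains T; converting to U", what), call. = FALSE)
    x <- gsub("T", "U", x, fixed = TRUE)
  }
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    sym <- unique(unlist(strsplit(gsub("[ACGU]", "", x[bad]), "")))
    stop(sprintf("%s contains non-ACGU symbols after conversion: %s",
                 what, paste(sym, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Reverse complement of RNA sequences
#'
#' @param x Character vector over {A,C,G,U}.
#' @return Character vector of antiparallel complements, 5'->3'.
#' @export
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

WC_PARTNER <- c(A = "U", C = "G", G = "C", U = "A")

is_wc_pair <- function(a, b) WC_PARTNER[a] == b

# G-U wobble counts as a pair in folding only, never in identity/mismatch
# counting or duplex energetics.
can_fold_pair <- function(a, b) {
  (WC_PARTNER[a] == b) | (a == "G" & b == "U") | (a == "U" & b == "G")
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): unequal lengths", call. = FALSE)
  sum(seq_chars(a) != seq_chars(b))
}
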