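#' Half-open genomic-style interval
#'
#' Internal coordinate carrier used for arms, loops and target windows.
#' Coordinates are 0-based half-open (`[start, end)`) so that bond indices
#' (cleavage sites) fall between `end - 1` and `end` without off-by-one
#' arithmetic. Printing is 1-based inclusive, the convention used in all
#' user-facing reports.
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `0 <= start < end`.
#' @return An object of class `interval` with fields `start` and `end`.
#' @examples
#' iv <- interval(4, 8)
#' iv_length(iv)  # 4
#' @export
interval <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("interval() takes scalar, non-missing start/end", call. = FALSE)
  }
  if (start < 0L || start >= end) {
    stop(sprintf("invalid interval [%d, %d): need 0 <= start < end", start, end),
         call. = FALSE)
  }
  structure(list(start = start, end = end), class = "interval")
}

#' @rdname interval
#' @param x An `interval`.
#' @export
iv_length <- function(x) x$end - x$start

#' @exportS3Method base::format
format.interval <- function(x, ...) {
  # printed 1-based inclusive
  sprintf("%d-%d", x$start + 1L, x$end)
}

#' @export
print.interval <- function(x, ...) {
  cat("<interval> ", format(x), " (", iv_length(x), " nt)\n", sep = "")
  invisible(x)
}

iv_overlaps <- function(a, b) a$start < b$end && b$start < a$end

iv_contains_bond <- function(x, bond) bond > x$start && bond < x$end

#' Extract the subsequence covered by an interval
#'
#' @param seq A single RNA string.
#' @param iv An [interval()].
#' @return Character scalar.
#' @export
iv_subseq <- function(seq, iv) {
  if (iv$end > nchar(seq)) stop("interval exceeds sequence bounds", call. = FALSE)
  substr(seq, iv$start + 1L, iv$end)
}
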