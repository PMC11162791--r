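#' Parse and annotate a pre-miRNA hairpin
#'
#' Builds the annotated precursor record used throughout the design
#' workflow: the validated RNA sequence, the mature-arm intervals, the
#' derived apical loop and the two Dicer cleavage bonds. The cleavage bonds
#' are derived from the mature-arm annotations (the bond at the 3' end of
#' the 5p arm and the bond at the 5' start of the 3p arm), matching how
#' processing sites are conventionally marked on precursor structures, and
#' are deliberately independent of the secondary structure.
#'
#' @param sequence RNA string (T is auto-converted to U with a warning).
#' @param arm5p,arm3p [interval()]s of the mature 5p/3p arms (0-based
#'   half-open; see [read_arms_tsv()] for the 1-based file convention).
#' @param name Record label.
#' @param structure Optional dot-bracket string of the same length as
#'   `sequence`, with balanced, non-crossing brackets.
#' @return An object of class `premirna_hairpin` with fields `name`,
#'   `sequence`, `arm5p`, `arm3p`, `structure`, `loop` (an [interval()]),
#'   `site5p` and `site3p` (bond indices).
#' @examples
#' hp <- parse_hairpin("GGGGAAAACCCC", interval(0, 4), interval(8, 12),
#'                     name = "toy")
#' hp$site5p  # 4
#' @export
parse_hairpin <- function(sequence, arm5p, arm3p, name = "hairpin",
                          structure = NULL) {
  stopifnot(inherits(arm5p, "interval"), inherits(arm3p, "interval"))
  if (length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  sequence <- as_rna(sequence, what = sprintf("hairpin '%s'", name))
  n <- nchar(sequence)
  if (arm5p$end > n || arm3p$end > n) {
    stop("arm annotation exceeds sequence bounds", call. = FALSE)
  }
  if (arm5p$end > arm3p$start) {
    stop(sprintf("arms overlap or touch out of order: arm5p ends at %d, arm3p starts at %d",
                 arm5p$end, arm3p$start), call. = FALSE)
  }
  if (!is.null(structure)) {
    if (nchar(structure) != n) {
      stop("structure length does not match sequence length", call. = FALSE)
    }
    validate_dotbracket(structure)
  }
  hp <- structure(
    list(name = name, sequence = sequence, arm5p = arm5p, arm3p = arm3p,
         structure = structure, loop = NULL,
         site5p = arm5p$end, site3p = arm3p$start),
    class = "premirna_hairpin")
  hp$loop <- infer_loop(hp)
  hp
}

#' @export
print.premirna_hairpin <- function(x, ...) {
  cat(sprintf("<premirna_hairpin> %s (%d nt)\n", x$name, nchar(x$sequence)))
  cat(sprintf("  arm5p %s | loop %s (%d nt) | arm3p %s\n",
              format(x$arm5p), format(x$loop), iv_length(x$loop),
              format(x$arm3p)))
  cat(sprintf("  cleavage bonds: 5p after position %d, 3p before position %d (1-based)\n",
              x$site5p, x$site3p + 1L))
  invisible(x)
}

validate_dotbracket <- function(db) {
  ch <- seq_chars(db)
  if (any(!ch %in% c("(", ")", "."))) {
    stop("structure contains symbols other than '(', ')', '.'", call. = FALSE)
  }
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    stop("unbalanced brackets in structure", call. = FALSE)
  }
  invisible(TRUE)
}

# pair table of a dot-bracket: integer vector, 0 where unpaired, else the
# 1-based partner position
dotbracket_pairs <- function(db) {
  ch <- seq_chars(db)
  n <- length(ch)
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  partner
}

#' Derive the apical loop of a hairpin
#'
#' Returns the maximal unpaired run enclosed by the innermost (closing) base
#' pair of the hairpin's single terminal loop. Bulges and internal loops in
#' the stem are not part of the apical loop; this is what makes loop sizes
#' comparable across paralogs whose stems contain bulges. If the record has
#' no structure, a base-pair-maximisation fold ([nussinov_fold()]) is used
#' as fallback.
#'
#' @param hairpin A `premirna_hairpin`.
#' @return The loop [interval()].
#' @export
infer_loop <- function(hairpin) {
  stopifnot(inherits(hairpin, "premirna_hairpin"))
  db <- hairpin$structure
  if (is.null(db)) db <- nussinov_fold(hairpin$sequence)
  ch <- seq_chars(db)
  n <- length(ch)
  # terminal (hairpin) loops: maximal '.' runs directly enclosed by '(' ... ')'
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  term <- which(r$values == "." &
                  starts > 1L & ends < n &
                  ch[pmax(starts - 1L, 1L)] == "(" &
                  ch[pmin(ends + 1L, n)] == ")")
  if (length(term) == 0L) {
    stop(sprintf("structure of '%s' has no terminal loop", hairpin$name),
         call. = FALSE)
  }
  if (length(term) > 1L) {
    stop(sprintf("structure of '%s' is not a single hairpin (found %d terminal loops; multibranch structures are not supported)",
                 hairpin$name, length(term)), call. = FALSE)
  }
  loop <- interval(starts[term] - 1L, ends[term])
  if (loop$start < hairpin$site5p || loop$end > hairpin$site3p ||
      iv_overlaps(loop, hairpin$arm5p) || iv_overlaps(loop, hairpin$arm3p)) {
    stop(sprintf("inferred loop %s of '%s' is not strictly between the annotated arms",
                 format(loop), hairpin$name), call. = FALSE)
  }
  loop
}

#' Ungapped position-wise identity between two equal-length regions
#'
#' No alignment is performed; the caller supplies homologous, equal-length
#' regions (e.g. the concatenated stem arms of two paralogs).
#'
#' @param seq_a,seq_b RNA strings of equal length.
#' @return One-row tibble with `matches`, `length`, `identity_pct`.
#' @examples
#' region_identity("ACGU", "ACGA")$identity_pct  # 75
#' @export
region_identity <- function(seq_a, seq_b) {
  seq_a <- as_rna(seq_a, "seq_a"); seq_b <- as_rna(seq_b, "seq_b")
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("region_identity(): sequences must have equal length (no gapped alignment is performed)",
         call. = FALSE)
  }
  m <- sum(seq_chars(seq_a) == seq_chars(seq_b))
  n <- nchar(seq_a)
  tibble::tibble(matches = m, length = n, identity_pct = 100 * m / n)
}

#' Nucleotide composition of a sequence or hairpin region
#'
#' @param x RNA string, or a `premirna_hairpin`.
#' @param region Optional [interval()] restricting a hairpin to a region
#'   (e.g. its loop).
#' @return One-row tibble with `length`, `gc_pct`, `au_pct`
#'   (`gc_pct + au_pct == 100` exactly for ACGU input).
#' @export
composition_stats <- function(x, region = NULL) {
  if (inherits(x, "premirna_hairpin")) {
    s <- if (is.null(region)) x$sequence else iv_subseq(x$sequence, region)
  } else {
    s <- if (is.null(region)) x else iv_subseq(x, region)
  }
  s <- as_rna(s)
  if (!nzchar(s)) stop("composition_stats(): empty region", call. = FALSE)
  ch <- seq_chars(s)
  n <- length(ch)
  gc <- sum(ch %in% c("G", "C"))
  gc_pct <- 100 * gc / n
  # complement computed as 100 - gc_pct so the partition is exact in floats
  tibble::tibble(length = n, gc_pct = gc_pct, au_pct = 100 - gc_pct)
}

#' Maximum base-pair secondary structure (fold fallback)
#'
#' Base-pair maximisation over Watson-Crick plus G-U pairs with a minimum
#' hairpin-loop size, by the classic O(n^3) dynamic programme. Used only as
#' a fallback when a record carries no dot-bracket structure; it is not a
#' thermodynamic (MFE) folder. The traceback is deterministic: pairing of
#' the interval's 3' end is preferred over leaving it unpaired, and the
#' 5'-most admissible partner is chosen on ties.
#'
#' @param sequence RNA string.
#' @param min_loop Minimum number of unpaired positions enclosed by a pair.
#' @return Dot-bracket string; short inputs return all-unpaired.
#' @examples
#' nussinov_fold("GGGAAACCC")  # "(((...)))"
#' @export
nussinov_fold <- function(sequence, min_loop = 3) {
  s <- seq_chars(as_rna(sequence))
  n <- length(s)
  if (n < min_loop + 2) return(strrep(".", n))
  M <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]  # j unpaired
      ls <- i:(j - min_loop - 1L)
      ok <- ls[can_fold_pair(s[ls], s[j])]
      for (l in ok) {
        left <- if (l > i) M[i, l - 1L] else 0L
        inner <- if (l + 1L <= j - 1L) M[l + 1L, j - 1L] else 0L
        cand <- left + inner + 1L
        if (cand > best) best <- cand
      }
      M[i, j] <- best
    }
  }
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i <= min_loop) next
    paired <- FALSE
    ls <- i:(j - min_loop - 1L)
    ok <- ls[can_fold_pair(s[ls], s[j])]
    for (l in ok) {  # ascending: 5'-most partner wins ties
      left <- if (l > i) M[i, l - 1L] else 0L
      inner <- if (l + 1L <= j - 1L) M[l + 1L, j - 1L] else 0L
      if (left + inner + 1L == M[i, j]) {
        db[l] <- "("; db[j] <- ")"
        if (l > i) stack[[length(stack) + 1L]] <- c(i, l - 1L)
        stack[[length(stack) + 1L]] <- c(l + 1L, j - 1L)
        paired <- TRUE
        break
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i, j - 1L)
  }
  paste(db, collapse = "")
}

# count of base pairs in a dot-bracket
n_pairs <- function(db) sum(seq_chars(db) == "(")
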