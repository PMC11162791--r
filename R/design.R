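#' Enumerate precursor-selective ASO candidates on a hairpin
#'
#' Two candidate classes are produced, mirroring the two design geometries
#' that work on paralogous precursors:
#' \describe{
#'   \item{`cleavage_overlap`}{every window of length `k` whose interval
#'     contains the Dicer cleavage bond of the chosen side with at least
#'     `min_side` nt on each side of the bond AND overlaps the apical loop
#'     by at least 1 nt;}
#'   \item{`loop_covering`}{exactly one window: the apical loop extended by
#'     `loop_flank` nt on each side (length `loop + 2 * loop_flank`,
#'     overriding `k`) — an 11-nt loop thus yields a 13-nt oligomer and a
#'     16-nt loop an 18-nt one.}
#' }
#' Each candidate's sequence is the reverse complement of its window.
#' By default only the 5' (5p-arm) cleavage bond is targeted; `site = "3p"`
#' enumerates the symmetric case.
#'
#' @param hairpin A [parse_hairpin()] record.
#' @param k Oligomer length for the cleavage class (>= 8).
#' @param classes Candidate classes to enumerate.
#' @param loop_flank Flank (nt) added to each side of the loop window.
#' @param min_side Minimum nt on each side of the cleavage bond.
#' @param site Which cleavage bond the `cleavage_overlap` class straddles.
#' @return Tibble: `precursor`, `class`, `window_start`, `window_end`
#'   (1-based inclusive), `target_site`, `sequence` (the antisense
#'   oligomer), `length`.
#' @export
enumerate_candidates <- function(hairpin, k = 13,
                                 classes = c("cleavage_overlap", "loop_covering"),
                                 loop_flank = 1, min_side = 2,
                                 site = c("5p", "3p")) {
  stopifnot(inherits(hairpin, "premirna_hairpin"))
  site <- match.arg(site)
  classes <- match.arg(classes, several.ok = TRUE)
  k <- as.integer(k)
  if (k < 8L) stop("enumerate_candidates(): k must be >= 8", call. = FALSE)
  n <- nchar(hairpin$sequence)
  loop <- hairpin$loop
  rows <- list()
  if ("cleavage_overlap" %in% classes) {
    bond <- if (site == "5p") hairpin$site5p else hairpin$site3p
    starts0 <- 0:(n - k)  # 0-based window starts
    keep <- vapply(starts0, function(s) {
      w <- interval(s, s + k)
      iv_contains_bond(w, bond) &&
        (bond - w$start) >= min_side && (w$end - bond) >= min_side &&
        iv_overlaps(w, loop)
    }, logical(1))
    for (s in starts0[keep]) {
      rows[[length(rows) + 1L]] <- candidate_row(hairpin, interval(s, s + k),
                                                 "cleavage_overlap")
    }
  }
  if ("loop_covering" %in% classes) {
    s <- loop$start - as.integer(loop_flank)
    e <- loop$end + as.integer(loop_flank)
    if (s < 0L || e > n) {
      warning(sprintf("loop_covering window [%d, %d) exceeds '%s' bounds; skipped",
                      s, e, hairpin$name), call. = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- candidate_row(hairpin, interval(s, e),
                                                 "loop_covering")
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(precursor = character(), class = character(),
                          window_start = integer(), window_end = integer(),
                          target_site = character(), sequence = character(),
                          length = integer()))
  }
  dplyr::bind_rows(rows)
}

candidate_row <- function(hairpin, window, class) {
  tsite <- iv_subseq(hairpin$sequence, window)
  tibble::tibble(precursor = hairpin$name,
                 class = class,
                 window_start = window$start + 1L,
                 window_end = window$end,
                 target_site = tsite,
                 sequence = rna_revcomp(tsite),
                 length = nchar(tsite))
}

#' Score candidates: duplex energy, self-structure, off-targets
#'
#' Fills in, for every candidate, the on-target duplex energy, the
#' self-structure screen of the oligomer, off-target hit counts against
#' the reference index, and the minimum mismatch to the sibling
#' precursor(s) with the selectivity verdict.
#'
#' @param candidates Tibble from [enumerate_candidates()].
#' @param params [nn_params()].
#' @param index Optional [build_index()] of the reference transcriptome.
#' @param paralogs Named character vector of sibling precursor sequences to
#'   discriminate against.
#' @param threshold Selectivity threshold (mismatches).
#' @return The candidate tibble with columns `dg37`, `dh`, `ds`,
#'   `hairpin_flag`, `homodimer_flag`, `longest_selfcomp_run`,
#'   `hits_v0..2`, `paralog_min_mm`, `dg_ratio`, `selectivity_pass`.
#' @export
score_candidates <- function(candidates, params = nn_params(), index = NULL,
                             paralogs = character(), threshold = 2) {
  if (nrow(candidates) == 0L) return(candidates)
  if (!is.null(index)) {
    off_len <- candidates$length != index$k
    if (any(off_len)) {
      message(sprintf("%d candidate(s) differ in length from the index k = %d; their transcriptome hit counts are reported as NA",
                      sum(off_len), index$k))
    }
  }
  scored <- purrr::pmap(
    list(candidates$sequence, candidates$target_site),
    function(oligo, tsite) {
      e <- duplex_energy(oligo, tsite, params)
      s <- self_structure(oligo, params)
      cand_index <- if (!is.null(index) && index$k == nchar(oligo)) index
      ot <- offtarget_report(oligo, index = cand_index, paralogs = paralogs,
                             dg_on = e$dg37, params = params,
                             threshold = threshold)
      dplyr::bind_cols(
        tibble::tibble(dg37 = e$dg37, dh = e$dh, ds = e$ds),
        s[, c("hairpin_flag", "homodimer_flag", "longest_selfcomp_run")],
        ot[, setdiff(names(ot), "dg_on")])
    })
  dplyr::bind_cols(candidates, dplyr::bind_rows(scored))
}

#' Annotate an oligomer with a 2'-OMe/LNA modification pattern
#'
#' The `"auto"` rule places LNA near both ends and in the middle of the
#' strand — 1-based positions `{2, ceiling(L / 2), L - 1}` for length `L` —
#' the placement known to raise target affinity; all remaining residues are
#' 2'-O-methyl. An explicit integer vector of 1-based positions may be
#' given instead. The annotation string prefixes LNA residues with `+`.
#'
#' @param candidates Candidate tibble (needs a `sequence` column), or a
#'   single sequence string.
#' @param spec `"auto"` or an integer vector of 1-based LNA positions.
#' @return The tibble with `lna_positions` (list-column) and `modified`
#'   (annotation string); for a single string, a one-row tibble.
#' @examples
#' apply_modification_pattern("ACGUACGUACGUA")$modified
#' @export
apply_modification_pattern <- function(candidates, spec = "auto") {
  if (is.character(candidates) && length(candidates) == 1L &&
      !is.data.frame(candidates)) {
    candidates <- tibble::tibble(sequence = as_rna(candidates))
  }
  ann <- purrr::map(candidates$sequence, function(s) {
    L <- nchar(s)
    pos <- if (identical(spec, "auto")) {
      sort(unique(c(2L, as.integer(ceiling(L / 2)), L - 1L)))
    } else {
      p <- as.integer(spec)
      if (any(p < 1L | p > L)) {
        stop(sprintf("LNA positions out of range 1..%d: %s", L,
                     paste(p[p < 1L | p > L], collapse = ", ")), call. = FALSE)
      }
      sort(unique(p))
    }
    ch <- seq_chars(s)
    ch[pos] <- paste0("+", ch[pos])
    list(pos = pos, txt = paste(ch, collapse = ""))
  })
  candidates$lna_positions <- purrr::map(ann, "pos")
  candidates$modified <- purrr::map_chr(ann, "txt")
  candidates$backbone <- "2OMe"
  candidates
}

#' Filter and rank scored candidates
#'
#' Hard filters first: the selectivity verdict must pass, and (unless
#' `keep_structured`) oligomers flagged for self-structure (hairpin or
#' homodimer) are dropped. Survivors are sorted by ascending on-target
#' `dg37` (strongest hybridization first), then ascending `hits_v1`, then
#' ascending `hits_v2`, with the sequence as a lexicographic final
#' tiebreak, and `rank` is assigned 1..n. The order is total and contains
#' no randomness.
#'
#' @param candidates Scored candidate tibble.
#' @param keep_structured Keep self-structured oligomers (default FALSE).
#' @return Object of class `ranked_design`: the ranked tibble with a
#'   `rank` column (plus attributes `n_input`, `n_filtered`, `warnings`).
#' @export
rank_candidates <- function(candidates, keep_structured = FALSE) {
  n_input <- nrow(candidates)
  warn <- character()
  out <- candidates
  if (n_input > 0L) {
    if (!all(c("dg37", "selectivity_pass") %in% names(out))) {
      stop("rank_candidates(): candidates must be scored first", call. = FALSE)
    }
    pass <- !is.na(out$selectivity_pass) & out$selectivity_pass
    out <- out[pass, , drop = FALSE]
    if (!keep_structured && nrow(out) > 0L) {
      out <- out[!(out$hairpin_flag | out$homodimer_flag), , drop = FALSE]
    }
    hv1 <- if ("hits_v1" %in% names(out)) dplyr::coalesce(out$hits_v1, 0L) else 0L
    hv2 <- if ("hits_v2" %in% names(out)) dplyr::coalesce(out$hits_v2, 0L) else 0L
    ord <- order(out$dg37, hv1, hv2, out$sequence, method = "radix")
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
  }
  if (nrow(out) == 0L) {
    warn <- c(warn, "no candidate survived the hard filters")
    warning("rank_candidates(): no candidate survived the hard filters",
            call. = FALSE)
  }
  structure(out, class = c("ranked_design", class(out)),
            n_input = n_input, n_filtered = n_input - nrow(out),
            warnings = warn)
}

#' One-call design workflow for a hairpin
#'
#' Enumerate, score, annotate and rank candidates against a reference index
#' and the sibling precursor(s).
#'
#' @inheritParams enumerate_candidates
#' @inheritParams score_candidates
#' @param modification `"auto"` or explicit LNA positions (see
#'   [apply_modification_pattern()]).
#' @param keep_structured Passed to [rank_candidates()].
#' @return A `ranked_design` tibble.
#' @export
design_asos <- function(hairpin, params = nn_params(), index = NULL,
                        paralogs = character(), k = 13,
                        classes = c("cleavage_overlap", "loop_covering"),
                        loop_flank = 1, min_side = 2, site = "5p",
                        threshold = 2, modification = "auto",
                        keep_structured = FALSE) {
  cand <- enumerate_candidates(hairpin, k = k, classes = classes,
                               loop_flank = loop_flank, min_side = min_side,
                               site = site)
  cand <- score_candidates(cand, params = params, index = index,
                           paralogs = paralogs, threshold = threshold)
  if (nrow(cand) > 0L) cand <- apply_modification_pattern(cand, modification)
  rank_candidates(cand, keep_structured = keep_structured)
}
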