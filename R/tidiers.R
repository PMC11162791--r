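#' Tidy a ranked design
#'
#' Returns the ranked candidate table as a plain tibble with the reporting
#' columns first.
#'
#' @param x A `ranked_design`.
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.ranked_design <- function(x, ...) {
  cols <- intersect(c("rank", "precursor", "class", "modified", "sequence",
                      "window_start", "window_end", "dg37", "hairpin_flag",
                      "homodimer_flag", "hits_v0", "hits_v1", "hits_v2",
                      "paralog_min_mm", "dg_ratio", "selectivity_pass"),
                    names(x))
  out <- tibble::as_tibble(x)[, c(cols, setdiff(names(x), cols))]
  out
}

#' One-row summary of a ranked design
#'
#' @param x A `ranked_design`.
#' @param ... Unused.
#' @return Tibble: `n_candidates`, `n_ranked`, `n_filtered_out`, `best_dg37`,
#'   `best_sequence`, `all_selective`.
#' @export
glance.ranked_design <- function(x, ...) {
  tibble::tibble(
    n_candidates = attr(x, "n_input"),
    n_ranked = nrow(x),
    n_filtered_out = attr(x, "n_filtered"),
    best_dg37 = if (nrow(x) > 0) x$dg37[x$rank == 1] else NA_real_,
    best_sequence = if (nrow(x) > 0) x$sequence[x$rank == 1] else NA_character_,
    all_selective = if (nrow(x) > 0) all(x$selectivity_pass) else NA)
}

#' Tidy a control pool
#'
#' @param x A `control_pool`.
#' @param ... Unused.
#' @return The controls tibble with the trace columns attached via
#'   attributes left intact.
#' @export
tidy.control_pool <- function(x, ...) x$controls

#' One-row summary of a control-design run
#'
#' @param x A `control_pool`.
#' @param ... Unused.
#' @return Tibble: `final_v`, `pool_size`, `filtered_size`, `n_controls`,
#'   `seed`.
#' @export
glance.control_pool <- function(x, ...) {
  tibble::tibble(final_v = x$final_v, pool_size = length(x$pool),
                 filtered_size = length(x$filtered),
                 n_controls = nrow(x$controls), seed = x$seed)
}
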