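#' Exhaustive k-mer candidate space
#'
#' The space of all `4^k` potential target sites (PTS), carried as 2-bit
#' packed integer codes `0 .. 4^k - 1`; iteration order is ascending code,
#' which equals lexicographic A < C < G < U order. The in-core bitset guard
#' allows `k <= 16` (a `4^16`-bit set is ~0.5 GB; `k = 13` needs ~8 MB).
#'
#' @param k Site length (1..16).
#' @return Object of class `candidate_space`: `k`, `total`.
#' @examples
#' enumerate_space(13)$total  # 67108864
#' @export
enumerate_space <- function(k) {
  k <- as.integer(k)
  if (k < 1L || k > 16L) {
    stop("enumerate_space(): k must be in 1..16 (in-core bitset guard)",
         call. = FALSE)
  }
  structure(list(k = k, total = 4^k), class = "candidate_space")
}

#' @export
print.candidate_space <- function(x, ...) {
  cat(sprintf("<candidate_space> k = %d; 4^%d = %s sites\n", x$k, x$k,
              format(x$total, big.mark = ",")))
  invisible(x)
}

#' Iterative elimination of candidate sites by alignment
#'
#' For each mismatch allowance `v` in the schedule (default 0, 1, 2),
#' candidates that align to the reference with at most `v` mismatches are
#' eliminated; the unaligned survivors of one round are the input of the
#' next, so survivor sets shrink monotonically. The elimination is
#' performed from the reference side (marking the Hamming-`<= v`
#' neighborhood of every indexed window in a `4^k` bitset), which is
#' set-equal to querying each candidate but far cheaper when the reference
#' is smaller than the space. The pool passed onward is the survivor set of
#' the largest `v` with a non-empty survivor set.
#'
#' @param space [enumerate_space()] result.
#' @param index [build_index()] result with `index$k == space$k`.
#' @param v_schedule Increasing mismatch allowances.
#' @param max_pool At most this many survivor sequences are decoded into
#'   the pool (ascending code order, with a warning if the cap binds);
#'   trace counts are exact regardless.
#' @return List of class `elimination_result`: `trace` (tibble `v`,
#'   `input_count`, `aligned_count`, `survivor_count`), `final_v`, `pool`
#'   (character vector of surviving target sites), `pool_truncated`.
#' @export
eliminate_by_alignment <- function(space, index, v_schedule = c(0, 1, 2),
                                   max_pool = 50000) {
  stopifnot(inherits(space, "candidate_space"),
            inherits(index, "transcriptome_index"))
  if (index$k != space$k) {
    stop(sprintf("index k = %d does not match space k = %d", index$k, space$k),
         call. = FALSE)
  }
  v_schedule <- as.integer(v_schedule)
  if (is.unsorted(v_schedule, strictly = TRUE)) {
    stop("v_schedule must be strictly increasing", call. = FALSE)
  }
  k <- space$k
  total <- space$total
  codes <- unique(index$postings$code)
  bits <- raw(ceiling(total / 8))
  trace <- vector("list", length(v_schedule))
  survivors <- total
  final_v <- NA_integer_
  for (i in seq_along(v_schedule)) {
    v <- v_schedule[i]
    if (length(codes) > 0) mark_ball(bits, codes, k, v)
    marked <- bitset_count(bits, total)
    surv <- total - marked
    trace[[i]] <- tibble::tibble(v = v, input_count = survivors,
                                 aligned_count = survivors - surv,
                                 survivor_count = surv)
    if (surv > 0) final_v <- v
    survivors <- surv
  }
  pool <- character(0)
  truncated <- FALSE
  if (!is.na(final_v)) {
    # re-mark up to final_v on a fresh bitset (bits may now hold a later round)
    fb <- raw(ceiling(total / 8))
    if (length(codes) > 0) mark_ball(fb, codes, k, final_v)
    n_surv <- total - bitset_count(fb, total)
    stride <- max(1, ceiling(n_surv / max_pool))
    if (stride > 1) {
      truncated <- TRUE
      warning(sprintf("survivor pool capped: decoding %d of %.0f survivors (every %d-th, ascending code order)",
                      as.integer(max_pool), n_surv, as.integer(stride)),
              call. = FALSE)
    }
    surv_codes <- bitset_extract(fb, total, max_pool, FALSE, stride)
    pool <- decode_kmers(surv_codes, k)
  }
  structure(list(trace = dplyr::bind_rows(trace), final_v = final_v,
                 pool = pool, pool_truncated = truncated),
            class = "elimination_result")
}

#' @export
print.elimination_result <- function(x, ...) {
  cat("<elimination_result>\n")
  print(x$trace)
  cat(sprintf("final_v = %s; pool of %d site(s)%s\n",
              ifelse(is.na(x$final_v), "none", x$final_v), length(x$pool),
              if (x$pool_truncated) " (truncated)" else ""))
  invisible(x)
}

#' Remove sequences with ASO-unfavorable characteristics
#'
#' Rejects candidate sites with (i) a mononucleotide run longer than
#' `max_nt_run` (default: three or more consecutive identical
#' nucleotides), (ii) a tandem dinucleotide repeat longer than
#' `max_dinuc_repeat` units (default: a 2-nt unit three or more times in a
#' row, e.g. ACACAC), or (iii) a homoduplex tendency, operationalized as a
#' perfect self-antiparallel complementary run of `dimer_run_min` or more
#' (the [self_structure()] homodimer screen).
#'
#' @param pool Character vector of candidate sites.
#' @param params [nn_params()] (for the homodimer energy).
#' @param max_nt_run Longest allowed mononucleotide run.
#' @param max_dinuc_repeat Longest allowed tandem dinucleotide repeat
#'   (units).
#' @param dimer_run_min Self-complementary run length that flags a
#'   homoduplex.
#' @return List: `filtered` (surviving sites), `rejections` (tibble `rule`,
#'   `n_rejected`; a sequence may be counted under several rules).
#' @export
filter_characteristics <- function(pool, params = nn_params(),
                                   max_nt_run = 2, max_dinuc_repeat = 2,
                                   dimer_run_min = 5) {
  if (length(pool) == 0L) stop("filter_characteristics(): empty pool", call. = FALSE)
  pool <- as_rna(pool, "pool")
  mono_re <- sprintf("([ACGU])\\1{%d,}", max_nt_run)
  di_re <- sprintf("([ACGU]{2})\\1{%d,}", max_dinuc_repeat)
  mono <- grepl(mono_re, pool)
  di <- grepl(di_re, pool)
  dimer <- vapply(pool, function(s) longest_selfcomp_run(s)$len >= dimer_run_min,
                  logical(1), USE.NAMES = FALSE)
  keep <- !(mono | di | dimer)
  list(
    filtered = pool[keep],
    rejections = tibble::tibble(
      rule = c("mononucleotide_run", "dinucleotide_repeat", "homodimer"),
      n_rejected = c(sum(mono), sum(di), sum(dimer))))
}

#' Emit negative-control oligomers from the filtered pool
#'
#' Each filtered target site is reverse-complemented into its antisense
#' control oligomer; `n` controls are then drawn by seeded uniform choice
#' (the seed is recorded in the output) and annotated with the standard
#' modification pattern.
#'
#' @param filtered Character vector of surviving sites.
#' @param n Number of controls to emit.
#' @param seed Integer seed (mandatory; recorded in the result).
#' @param modification Passed to [apply_modification_pattern()].
#' @return Tibble: `name`, `target_site`, `sequence`, `modified`,
#'   `lna_positions`, `seed`.
#' @export
emit_controls <- function(filtered, n = 1, seed, modification = "auto") {
  if (length(filtered) == 0L) {
    stop("emit_controls(): empty filtered pool; relax k or the mismatch schedule",
         call. = FALSE)
  }
  if (missing(seed)) stop("emit_controls(): seed is mandatory", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L || n > length(filtered)) {
    stop(sprintf("emit_controls(): n must be in 1..%d", length(filtered)),
         call. = FALSE)
  }
  idx <- local_seeded(seed, sample.int(length(filtered), n))
  out <- tibble::tibble(
    name = sprintf("ctrl_%02d", seq_len(n)),
    target_site = filtered[idx],
    sequence = rna_revcomp(filtered[idx]))
  out <- apply_modification_pattern(out, modification)
  out$seed <- as.integer(seed)
  out
}

# run expr under a local RNG state seeded with `seed`
local_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Full negative-control design pipeline
#'
#' [enumerate_space()] -> [eliminate_by_alignment()] ->
#' [filter_characteristics()] -> [emit_controls()], returning the controls
#' together with the complete elimination/filter trace.
#'
#' @param index [build_index()] of the reference transcriptome.
#' @param k Site length.
#' @param v_schedule Mismatch allowances (increasing).
#' @param n Number of controls.
#' @param seed Mandatory integer seed.
#' @param params [nn_params()].
#' @param max_pool Survivor decoding cap (see [eliminate_by_alignment()]).
#' @param ... Passed to [filter_characteristics()].
#' @return Object of class `control_pool`: `controls` (tibble), `pool`,
#'   `filtered`, `trace`, `final_v`, `rejections`, `seed`.
#' @export
design_controls <- function(index, k = 13, v_schedule = c(0, 1, 2), n = 1,
                            seed, params = nn_params(), max_pool = 50000, ...) {
  if (missing(seed)) stop("design_controls(): seed is mandatory", call. = FALSE)
  space <- enumerate_space(k)
  elim <- eliminate_by_alignment(space, index, v_schedule = v_schedule,
                                 max_pool = max_pool)
  if (length(elim$pool) == 0L) {
    stop("design_controls(): no candidate site survived any round", call. = FALSE)
  }
  filt <- filter_characteristics(elim$pool, params = params, ...)
  controls <- emit_controls(filt$filtered, n = n, seed = seed)
  structure(list(controls = controls, pool = elim$pool,
                 filtered = filt$filtered, trace = elim$trace,
                 final_v = elim$final_v, rejections = filt$rejections,
                 seed = as.integer(seed),
                 pool_truncated = elim$pool_truncated),
            class = "control_pool")
}

#' @export
print.control_pool <- function(x, ...) {
  cat(sprintf("<control_pool> final_v = %d; pool %d -> filtered %d -> %d control(s); seed %d\n",
              x$final_v, length(x$pool), length(x$filtered),
              nrow(x$controls), x$seed))
  print(x$trace)
  invisible(x)
}
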