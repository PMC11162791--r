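#' Build a k-mer index over a reference transcriptome
#'
#' Indexes every length-`k` window of the reference (and, by default, of
#' its reverse complement) for the exact ungapped mismatch search used in
#' off-target screening and control design. Windows containing ambiguity
#' symbols (N etc.) are excluded and counted; transcripts shorter than `k`
#' are skipped with a warning.
#'
#' @param transcripts Named character vector of sequences, or a tibble with
#'   columns `id` and `seq` (as returned by [read_fasta()] or
#'   [generate_synthetic_transcriptome()]).
#' @param k Word length (4..16).
#' @param both_orientations Index the reverse complement too (default TRUE,
#'   the conservative aligner-default behaviour); set FALSE for
#'   strand-specific reasoning.
#' @return An object of class `transcriptome_index`: `k`, `records` (tibble
#'   `id`, `length`), `postings` (tibble `code`, `tid`, `offset`, `strand`),
#'   `codes_sorted`, `orientations`, `n_skipped_windows`.
#' @export
build_index <- function(transcripts, k = 13, both_orientations = TRUE) {
  if (is.data.frame(transcripts)) {
    ids <- transcripts$id
    seqs <- transcripts$seq
  } else {
    ids <- names(transcripts)
    if (is.null(ids)) ids <- paste0("tx", seq_along(transcripts))
    seqs <- unname(transcripts)
  }
  k <- as.integer(k)
  if (k < 4L || k > 16L) stop("build_index(): k must be in 4..16", call. = FALSE)
  seqs <- toupper(gsub("T", "U", toupper(seqs), fixed = TRUE))
  too_short <- nchar(seqs) < k
  if (any(too_short)) {
    warning(sprintf("%d transcript(s) shorter than k = %d skipped: %s",
                    sum(too_short), k,
                    paste(utils::head(ids[too_short], 5), collapse = ", ")),
            call. = FALSE)
  }
  strands <- if (both_orientations) c("+", "-") else "+"
  posts <- purrr::map(which(!too_short), function(i) {
    purrr::map(strands, function(st) {
      s <- if (st == "+") seqs[i] else rna_revcomp(seqs[i])
      codes <- window_codes(s, k)
      tibble::tibble(code = codes, tid = i,
                     offset = seq_along(codes) - 1L, strand = st)
    })
  })
  empty <- tibble::tibble(code = numeric(), tid = integer(),
                          offset = integer(), strand = character())
  postings <- dplyr::bind_rows(empty, purrr::flatten(posts))
  n_skipped <- sum(is.na(postings$code))
  postings <- postings[!is.na(postings$code), , drop = FALSE]
  postings <- dplyr::arrange(postings, .data$tid, .data$offset, .data$strand)
  structure(
    list(k = k,
         records = tibble::tibble(id = ids, length = nchar(seqs)),
         postings = postings,
         codes_sorted = sort(postings$code),
         orientations = strands,
         n_skipped_windows = n_skipped),
    class = "transcriptome_index")
}

#' @export
print.transcriptome_index <- function(x, ...) {
  cat(sprintf("<transcriptome_index> k = %d; %d transcript(s); %s posting(s); orientations: %s\n",
              x$k, nrow(x$records),
              format(nrow(x$postings), big.mark = ","),
              paste(x$orientations, collapse = "")))
  invisible(x)
}

#' Count indexed windows within v mismatches of a site
#'
#' Ungapped, end-to-end semantics: the number of indexed windows at Hamming
#' distance at most `v` from the query site (G-U counts as a mismatch).
#' Implemented by enumerating the mismatch neighborhood of the query
#' (size `sum(choose(k, 0:v) * 3^(0:v))`) and summing posting counts, which
#' is exact. Window occurrences are counted, not distinct transcripts; see
#' [per_transcript_hits()] for the per-transcript summary.
#'
#' @param site_seq Query site, 5'->3', length exactly `index$k`. Note this
#'   is the target site; for an oligomer use its reverse complement (see
#'   [offtarget_report()], which converts internally).
#' @param index A [build_index()] result.
#' @param v Maximum mismatches (0..3).
#' @return Integer hit count.
#' @export
count_hits <- function(site_seq, index, v) {
  stopifnot(inherits(index, "transcriptome_index"))
  site_seq <- as_rna(site_seq, "site_seq")
  if (nchar(site_seq) != index$k) {
    stop(sprintf("count_hits(): query length %d != index k = %d",
                 nchar(site_seq), index$k), call. = FALSE)
  }
  code <- encode_kmers(site_seq)
  nb <- neighbor_codes(code, index$k, as.integer(v))
  as.integer(count_codes_in_sorted(index$codes_sorted, nb))
}

#' Per-transcript hit summary at v mismatches
#'
#' @inheritParams count_hits
#' @return Tibble with `id`, `strand`, `hits`.
#' @export
per_transcript_hits <- function(site_seq, index, v) {
  stopifnot(inherits(index, "transcriptome_index"))
  site_seq <- as_rna(site_seq, "site_seq")
  code <- encode_kmers(site_seq)
  nb <- neighbor_codes(code, index$k, as.integer(v))
  hit <- index$postings[index$postings$code %in% nb, , drop = FALSE]
  hit$id <- index$records$id[hit$tid]
  dplyr::count(hit, .data$id, .data$strand, name = "hits")
}

#' Minimum mismatch count of an oligomer against a paralog
#'
#' Minimum Hamming distance between the oligomer's reverse complement (its
#' target site) and any window of the paralog sequence, forward
#' orientation. This is the quantity the precursor-selectivity rule is
#' applied to.
#'
#' @param aso Antisense oligomer, 5'->3'.
#' @param paralog_seq Paralog precursor sequence (at least as long as the
#'   oligomer).
#' @return Integer minimum mismatch count.
#' @export
min_mismatch_to_paralog <- function(aso, paralog_seq) {
  aso <- as_rna(aso, "aso")
  paralog_seq <- as_rna(paralog_seq, "paralog_seq")
  if (nchar(aso) > nchar(paralog_seq)) {
    stop("min_mismatch_to_paralog(): oligomer longer than paralog sequence",
         call. = FALSE)
  }
  min_hamming_window(rna_revcomp(aso), paralog_seq)$min_mm
}

#' Precursor-selectivity verdict
#'
#' An oligomer passes when its target region differs from the paralog by at
#' least `threshold` nucleotides (default 2), the mismatch margin observed
#' to prevent stable off-target hybridization for 13-mers of this
#' chemistry.
#'
#' @param paralog_min_mm Minimum mismatch count (from
#'   [min_mismatch_to_paralog()]).
#' @param threshold Required mismatches.
#' @return Logical.
#' @export
selectivity_check <- function(paralog_min_mm, threshold = 2) {
  if (any(is.na(paralog_min_mm))) {
    stop("selectivity_check(): paralog_min_mm must be computed first", call. = FALSE)
  }
  paralog_min_mm >= threshold
}

#' Full off-target report for one oligomer
#'
#' Convenience wrapper: converts the oligomer to its target site, counts
#' hits at v = 0..`max_v`, computes the paralog minimum mismatch and the
#' selectivity verdict, and (when paralogs are supplied) the on/off energy
#' ratio `dg_on / best cross-hybridization energy vs any paralog`.
#'
#' @param aso Antisense oligomer, 5'->3'.
#' @param index [build_index()] result (its `k` must equal `nchar(aso)` for
#'   hit counting; otherwise hit counts are `NA` with a warning).
#' @param paralogs Named character vector of paralog precursor sequences.
#' @param dg_on On-target duplex energy (kcal/mol), for the ratio.
#' @param params [nn_params()] for the off-target energy.
#' @param max_v Largest mismatch allowance.
#' @param threshold Selectivity threshold (mismatches).
#' @return One-row tibble: `hits_v0`..`hits_v<max_v>`, `paralog_min_mm`,
#'   `dg_on`, `dg_ratio`, `selectivity_pass`.
#' @export
offtarget_report <- function(aso, index = NULL, paralogs = character(),
                             dg_on = NA_real_, params = nn_params(),
                             max_v = 2, threshold = 2) {
  aso <- as_rna(aso, "aso")
  site <- rna_revcomp(aso)
  hits <- stats::setNames(rep(NA_integer_, max_v + 1L),
                          paste0("hits_v", 0:max_v))
  if (!is.null(index)) {
    if (index$k == nchar(aso)) {
      for (v in 0:max_v) hits[[paste0("hits_v", v)]] <- count_hits(site, index, v)
    } else {
      warning(sprintf("index k = %d != oligomer length %d; hit counts NA",
                      index$k, nchar(aso)), call. = FALSE)
    }
  }
  min_mm <- NA_integer_
  dg_ratio <- NA_real_
  if (length(paralogs) > 0) {
    min_mm <- min(vapply(paralogs, function(p) min_mismatch_to_paralog(aso, p),
                         integer(1)))
    if (!is.na(dg_on)) {
      dg_off <- suppressWarnings(
        min(vapply(paralogs, function(p) cross_hybridization(aso, p, params),
                   numeric(1)), na.rm = TRUE))
      if (is.finite(dg_off) && dg_off < 0) dg_ratio <- dg_on / dg_off
    }
  }
  tibble::tibble(!!!as.list(hits),
                 paralog_min_mm = min_mm,
                 dg_on = dg_on,
                 dg_ratio = dg_ratio,
                 selectivity_pass = if (is.na(min_mm)) NA else
                   selectivity_check(min_mm, threshold))
}
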