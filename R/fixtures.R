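#' Seeded synthetic transcriptome with planted sites and decoys
#'
#' Generates a reproducible background transcriptome for testing the
#' off-target and control pipelines without downloads. Planted sites are
#' inserted verbatim the requested number of copies; decoys are copies of a
#' site mutated at exactly the requested Hamming distance. Insertions
#' replace disjoint stretches of the random background, and the result is
#' verified post hoc: a regenerated draw is attempted (bounded retries) if
#' the random background accidentally recreates a planted site elsewhere.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_range Integer vector `c(min, max)` of transcript lengths.
#' @param seed Mandatory integer seed; the generator is a pure function of
#'   its arguments.
#' @param planted_sites Optional tibble with columns `sequence`, `copies`
#'   and `mismatches` (0 plants the site verbatim; d > 0 plants a decoy at
#'   exactly Hamming distance d).
#' @param gc Background G+C fraction.
#' @return Tibble `id`, `seq`, `source` plus attribute `"plants"` (tibble
#'   `sequence`, `planted`, `tid`, `offset`).
#' @export
generate_synthetic_transcriptome <- function(n_transcripts, length_range,
                                             seed, planted_sites = NULL,
                                             gc = 0.5) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(length_range) == 2, length_range[1] <= length_range[2])
  if (!is.null(planted_sites)) {
    need <- c("sequence", "copies", "mismatches")
    if (!all(need %in% names(planted_sites))) {
      stop(sprintf("planted_sites needs columns: %s", paste(need, collapse = ", ")),
           call. = FALSE)
    }
    planted_sites$sequence <- as_rna(planted_sites$sequence, "planted site")
    if (anyDuplicated(planted_sites$sequence)) {
      stop("each planted sequence may appear in one row only", call. = FALSE)
    }
    if (any(nchar(planted_sites$sequence) > length_range[1])) {
      stop("planted site longer than the shortest transcript", call. = FALSE)
    }
  }
  local_seeded(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
    for (attempt in 1:25) {
      lens <- if (length_range[1] == length_range[2]) {
        rep(length_range[1], n_transcripts)
      } else {
        sample(length_range[1]:length_range[2], n_transcripts, replace = TRUE)
      }
      seqs <- vapply(lens, function(L) {
        paste(sample(RNA_ALPHABET, L, replace = TRUE, prob = p), collapse = "")
      }, character(1))
      plants <- tibble::tibble(sequence = character(), planted = character(),
                               tid = integer(), offset = integer())
      if (!is.null(planted_sites) && nrow(planted_sites) > 0) {
        for (r in seq_len(nrow(planted_sites))) {
          site <- planted_sites$sequence[r]
          L <- nchar(site)
          for (cp in seq_len(planted_sites$copies[r])) {
            ins <- site
            d <- planted_sites$mismatches[r]
            if (d > 0) {
              pos <- sample.int(L, d)
              ch <- seq_chars(site)
              ch[pos] <- vapply(ch[pos], function(b) {
                sample(setdiff(RNA_ALPHABET, b), 1)
              }, character(1))
              ins <- paste(ch, collapse = "")
            }
            tid <- sample.int(n_transcripts, 1)
            off <- sample.int(nchar(seqs[tid]) - L + 1L, 1) - 1L
            substr(seqs[tid], off + 1L, off + L) <- ins
            plants <- dplyr::add_row(plants, sequence = site, planted = ins,
                                     tid = tid, offset = off)
          }
        }
      }
      if (verify_plants(seqs, planted_sites, plants)) {
        out <- tibble::tibble(id = sprintf("synthetic_tx_%04d",
                                           seq_len(n_transcripts)),
                              seq = seqs, source = "synthetic")
        attr(out, "plants") <- plants
        return(out)
      }
    }
    stop("could not satisfy planting constraints in 25 attempts; enlarge the background or shorten the sites",
         call. = FALSE)
  })
}

# post-hoc check: each planted copy occurs the requested number of times at
# the requested distance, with no accidental closer background match and no
# overwritten plants
verify_plants <- function(seqs, planted_sites, plants) {
  if (is.null(planted_sites) || nrow(planted_sites) == 0) return(TRUE)
  for (r in seq_len(nrow(planted_sites))) {
    site <- planted_sites$sequence[r]
    d <- planted_sites$mismatches[r]
    dists <- vapply(seqs, function(s) min_hamming_window(site, s)$min_mm,
                    numeric(1), USE.NAMES = FALSE)
    exact_hits <- sum(vapply(seqs, function(s) {
      sum(vapply(0:(nchar(s) - nchar(site)), function(off) {
        substr(s, off + 1L, off + nchar(site)) == site
      }, logical(1)))
    }, numeric(1)))
    if (d == 0) {
      if (exact_hits != planted_sites$copies[r]) return(FALSE)
    } else {
      if (min(dists) != d) return(FALSE)
    }
  }
  TRUE
}

#' Seeded pair of paralogous synthetic hairpins
#'
#' Emulates the geometry that makes paralog-selective design possible: two
#' hairpins whose stems are near-identical (configurable identity) while
#' the apical loops diverge in both length and composition (the first loop
#' balanced, the second A/U-rich). The mature 5p arms are kept identical
#' (paralogs of one miRNA family produce the same 5p miRNA), so identity
#' mutations are placed in the upper stem and the 3p side.
#'
#' @param stem_len Paired stem length per side (nt).
#' @param loop_len_a,loop_len_b Apical loop lengths (>= 3).
#' @param stem_identity_pct Target identity of the concatenated stems
#'   (50..100); achieved within one position.
#' @param seed Mandatory integer seed.
#' @param arm_len Mature-arm length (must leave >= 1 nt of upper stem).
#' @return List of class `paralog_fixture`: `hairpin_a`, `hairpin_b`
#'   (annotated `premirna_hairpin`s with structures), `stem_identity`
#'   (measured), `seed`.
#' @export
generate_paralog_hairpins <- function(stem_len = 23, loop_len_a = 11,
                                      loop_len_b = 16, stem_identity_pct = 92,
                                      seed, arm_len = 22) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(loop_len_a >= 3, loop_len_b >= 3,
            stem_identity_pct >= 50, stem_identity_pct <= 100)
  if (arm_len >= stem_len) {
    stop("arm_len must be smaller than stem_len (upper stem needed)", call. = FALSE)
  }
  n_stem <- 2L * stem_len
  n_mut <- round((1 - stem_identity_pct / 100) * n_stem)
  n_free <- (stem_len - arm_len) + stem_len  # upper 5' stem + whole 3' side
  if (n_mut > n_free) {
    stop("requested stem identity is infeasible with an identical 5p arm",
         call. = FALSE)
  }
  local_seeded(seed, {
    side5 <- paste(sample(RNA_ALPHABET, stem_len, replace = TRUE),
                   collapse = "")
    side3 <- rna_revcomp(side5)
    loop_a <- paste(sample(RNA_ALPHABET, loop_len_a, replace = TRUE,
                           prob = c(.25, .25, .25, .25)), collapse = "")
    loop_b <- paste(sample(RNA_ALPHABET, loop_len_b, replace = TRUE,
                           prob = c(.42, .08, .08, .42)), collapse = "")
    seq_a <- paste0(side5, loop_a, side3)
    # mutate n_mut stem positions of B outside the 5p arm
    free_pos <- c(if (stem_len > arm_len) (arm_len + 1L):stem_len,
                  (stem_len + 1L):n_stem)  # positions in concatenated stem
    mut <- sort(sample(free_pos, n_mut))
    stem_b <- seq_chars(paste0(side5, side3))
    stem_b[mut] <- vapply(stem_b[mut], function(b) {
      sample(setdiff(RNA_ALPHABET, b), 1)
    }, character(1))
    seq_b <- paste0(paste(stem_b[1:stem_len], collapse = ""), loop_b,
                    paste(stem_b[(stem_len + 1L):n_stem], collapse = ""))
    mk <- function(s, loop_len, name) {
      n <- nchar(s)
      parse_hairpin(
        s,
        arm5p = interval(0, arm_len),
        arm3p = interval(n - arm_len, n),
        name = name,
        structure = paste0(strrep("(", stem_len), strrep(".", loop_len),
                           strrep(")", stem_len)))
    }
    hp_a <- mk(seq_a, loop_len_a, "synthetic_paralog_a")
    hp_b <- mk(seq_b, loop_len_b, "synthetic_paralog_b")
    stems_a <- paste0(substr(seq_a, 1, stem_len),
                      substr(seq_a, stem_len + loop_len_a + 1L, nchar(seq_a)))
    stems_b <- paste0(substr(seq_b, 1, stem_len),
                      substr(seq_b, stem_len + loop_len_b + 1L, nchar(seq_b)))
    structure(list(hairpin_a = hp_a, hairpin_b = hp_b,
                   stem_identity = region_identity(stems_a, stems_b),
                   seed = as.integer(seed)),
              class = "paralog_fixture")
  })
}

#' @export
print.paralog_fixture <- function(x, ...) {
  cat(sprintf("<paralog_fixture> seed %s; stems %s\n",
              ifelse(is.na(x$seed), "NA", x$seed),
              if (is.null(x$stem_identity)) "of unequal length" else
                sprintf("%.1f%% identical", x$stem_identity$identity_pct)))
  print(x$hairpin_a); print(x$hairpin_b)
  invisible(x)
}
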