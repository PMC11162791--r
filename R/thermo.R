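T37_K <- 310.15
GAS_CONST_KCAL <- 1.987e-3  # kcal/(K*mol)

#' Load a nearest-neighbor RNA/RNA parameter set
#'
#' The bundled default is the standard Watson-Crick RNA/RNA set measured in
#' 1 M NaCl at 37 degrees C (the parameter basis shared by sequence-only
#' hybridization calculators). Alternates can be swapped in via a TSV with
#' columns `step`, `dh`, `ds`, `dg37`, where `step` covers all 16
#' Watson-Crick dinucleotide steps plus the `init` and `au_end` rows.
#' Modified residues (2'-OMe, LNA) carry no energetic bonus in this model;
#' they are design annotations only.
#'
#' @param path TSV file; default is the bundled 1 M NaCl set.
#' @return An object of class `nn_params`: `stacks` (named list of
#'   `c(dh, ds, dg37)`), `init`, `au_end`, `salt_label`, `version`.
#' @export
nn_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_rna_1M_NaCl_v1.tsv", package = "seloligo")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("step", "dh", "ds", "dg37")
  if (!all(need %in% names(tab))) {
    stop("parameter file must have columns step, dh, ds, dg37", call. = FALSE)
  }
  rows <- function(nm) {
    r <- tab[tab$step == nm, , drop = FALSE]
    if (nrow(r) != 1L) stop(sprintf("parameter file: expected one '%s' row", nm),
                            call. = FALSE)
    c(dh = r$dh, ds = r$ds, dg37 = r$dg37)
  }
  steps <- as.vector(outer(RNA_ALPHABET, RNA_ALPHABET, paste0))
  missing_steps <- setdiff(steps, tab$step)
  if (length(missing_steps) > 0L) {
    stop(sprintf("parameter file missing steps: %s",
                 paste(missing_steps, collapse = ", ")), call. = FALSE)
  }
  stacks <- lapply(stats::setNames(steps, steps), rows)
  p <- structure(
    list(stacks = stacks, init = rows("init"), au_end = rows("au_end"),
         salt_label = "1 M NaCl",
         version = sub("\\.tsv$", "", basename(path))),
    class = "nn_params")
  validate_nn_params(p)
  p
}

#' Check internal consistency of a parameter set
#'
#' Every entry (stacks, initiation, terminal penalty) must satisfy
#' `|dg37 - (dh - 310.15 * ds)| <= tol` kcal/mol.
#'
#' @param params An `nn_params`.
#' @param tol Tolerance in kcal/mol.
#' @return `params`, invisibly; errors on inconsistency.
#' @export
validate_nn_params <- function(params, tol = 0.05) {
  entries <- c(params$stacks, list(init = params$init, au_end = params$au_end))
  dev <- vapply(entries, function(e) {
    abs(e[["dg37"]] - (e[["dh"]] - T37_K * e[["ds"]]))
  }, numeric(1))
  if (any(dev > tol)) {
    bad <- names(entries)[dev > tol]
    stop(sprintf("inconsistent nearest-neighbor entries (|dG37 - (dH - 310.15 dS)| > %.2f): %s",
                 tol, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(params)
}

#' @export
print.nn_params <- function(x, ...) {
  cat(sprintf("<nn_params> %s (%s); 16 WC steps + init + AU-end\n",
              x$version, x$salt_label))
  invisible(x)
}

#' Hybridization energy of a fully complementary RNA/RNA duplex
#'
#' Nearest-neighbor sum: initiation + stacked dinucleotide terms + one
#' penalty per terminal A-U pair. The oligomer must be fully Watson-Crick
#' complementary (antiparallel) to the target site; G-U pairs and
#' mismatches are rejected, since designed oligomers are fully
#' complementary by construction and mismatched duplex thermodynamics are
#' out of scope. Predicted values are at the parameter set's salt
#' (`salt_label` is echoed); no salt correction is applied.
#'
#' @param oligo Antisense oligomer, 5'->3'.
#' @param target_site Target site, 5'->3', same length (>= 2).
#' @param params An [nn_params()].
#' @return One-row tibble: `dg37`, `dh`, `ds`, `length`, `salt`.
#' @examples
#' p <- nn_params()
#' duplex_energy("GC", "GC", p)  # init + one GC stack
#' @export
duplex_energy <- function(oligo, target_site, params = nn_params()) {
  oligo <- as_rna(oligo, "oligo")
  target_site <- as_rna(target_site, "target_site")
  n <- nchar(target_site)
  if (nchar(oligo) != n) {
    stop("duplex_energy(): oligo and target site must have equal length",
         call. = FALSE)
  }
  if (n < 2L) {
    stop("duplex_energy(): duplex needs length >= 2 (a single base pair has no stack)",
         call. = FALSE)
  }
  o <- seq_chars(oligo)
  t <- seq_chars(target_site)
  # antiparallel: oligo position i pairs target position n + 1 - i
  mism <- which(WC_PARTNER[t] != rev(o))
  if (length(mism) > 0L) {
    stop(sprintf("duplex_energy(): non-Watson-Crick pair at target position %d (%s vs oligo %s)",
                 mism[1], t[mism[1]], rev(o)[mism[1]]), call. = FALSE)
  }
  dh <- params$init[["dh"]]; ds <- params$init[["ds"]]; dg <- params$init[["dg37"]]
  for (i in seq_len(n - 1L)) {
    e <- params$stacks[[paste0(t[i], t[i + 1L])]]
    dh <- dh + e[["dh"]]; ds <- ds + e[["ds"]]; dg <- dg + e[["dg37"]]
  }
  n_au_ends <- sum(t[c(1L, n)] %in% c("A", "U"))
  dh <- dh + n_au_ends * params$au_end[["dh"]]
  ds <- ds + n_au_ends * params$au_end[["ds"]]
  dg <- dg + n_au_ends * params$au_end[["dg37"]]
  tibble::tibble(dg37 = dg, dh = dh, ds = ds, length = n,
                 salt = params$salt_label)
}

#' Two-state concentration-dependent melting temperature
#'
#' `Tm(K) = dH / (dS + R ln(CT / a))` with `R = 1.987e-3` kcal/(K*mol),
#' `a = 4` for non-self-complementary duplexes and `a = 1` for
#' self-complementary ones; returned in degrees C.
#'
#' @param energy One-row tibble from [duplex_energy()] (fields `dh`, `ds`),
#'   or a list with those fields.
#' @param ct Total strand concentration (M).
#' @param self_complementary Logical.
#' @return Tm in degrees C.
#' @export
predict_tm <- function(energy, ct, self_complementary = FALSE) {
  dh <- energy$dh; ds <- energy$ds
  if (!is.finite(dh) || !is.finite(ds) || dh >= 0 || ds >= 0) {
    stop("predict_tm(): needs dh < 0 and ds < 0", call. = FALSE)
  }
  if (!is.finite(ct) || ct <= 0) stop("predict_tm(): ct must be > 0", call. = FALSE)
  a <- if (self_complementary) 1 else 4
  denom <- ds + GAS_CONST_KCAL * log(ct / a)
  if (denom >= 0) {
    stop("predict_tm(): no two-state melting in range (non-negative denominator)",
         call. = FALSE)
  }
  dh / denom - 273.15
}

#' Self-structure screen of an oligomer
#'
#' Flags single-strand folding (a helix of `hairpin_min_stem` or more
#' nested pairs in the base-pair-maximisation fold) and homodimerisation
#' (longest perfect self-antiparallel complementary run of
#' `dimer_run_min` or more). The homodimer energy is the duplex energy of
#' that run only; this is a deterministic screening proxy, not an
#' internal-loop model.
#'
#' @param oligo RNA string (length >= 2).
#' @param params [nn_params()].
#' @param hairpin_min_stem Minimum nested-helix length to flag folding.
#' @param dimer_run_min Minimum self-complementary run to flag dimers.
#' @return One-row tibble: `hairpin_flag`, `hairpin_stem_len`,
#'   `homodimer_flag`, `homodimer_dg37`, `longest_selfcomp_run`.
#' @export
self_structure <- function(oligo, params = nn_params(),
                           hairpin_min_stem = 4, dimer_run_min = 5) {
  oligo <- as_rna(oligo, "oligo")
  if (nchar(oligo) < 2L) stop("self_structure(): oligo too short", call. = FALSE)
  db <- nussinov_fold(oligo)
  stem <- longest_helix(db)
  best <- longest_selfcomp_run(oligo)
  dimer_flag <- best$len >= dimer_run_min
  dimer_dg <- NA_real_
  if (dimer_flag) {
    sub <- substr(oligo, best$start, best$start + best$len - 1L)
    dimer_dg <- duplex_energy(sub, rna_revcomp(sub), params)$dg37
  }
  tibble::tibble(
    hairpin_flag = stem >= hairpin_min_stem,
    hairpin_stem_len = stem,
    homodimer_flag = dimer_flag,
    homodimer_dg37 = dimer_dg,
    longest_selfcomp_run = best$len)
}

# longest run of directly nested pairs (i,j),(i+1,j-1),... in a dot-bracket
longest_helix <- function(db) {
  partner <- dotbracket_pairs(db)
  best <- 0L
  i <- 1L
  n <- length(partner)
  while (i <= n) {
    j <- partner[i]
    if (j > i) {
      run <- 1L
      while (i + run <= n && partner[i + run] == j - run && j - run > i + run) {
        run <- run + 1L
      }
      best <- max(best, run)
      i <- i + run
    } else {
      i <- i + 1L
    }
  }
  best
}

# longest perfect WC-complementary run of s against itself in antiparallel
# orientation, over all offsets; returns 1-based start of the run in s
longest_selfcomp_run <- function(s) {
  ch <- seq_chars(s)
  n <- length(ch)
  best_len <- 0L; best_start <- 1L
  # positions i (in s) pairing positions j (in s) with i + j = const
  for (const in 2L:(2L * n)) {
    run <- 0L
    lo <- max(1L, const - n)
    hi <- min(n, const - 1L)
    for (i in lo:hi) {
      j <- const - i
      if (WC_PARTNER[ch[i]] == ch[j]) {
        run <- run + 1L
        if (run > best_len) {
          best_len <- run
          best_start <- i - run + 1L
        }
      } else run <- 0L
    }
  }
  list(len = best_len, start = best_start)
}

#' Best cross-hybridization energy between two oligomers
#'
#' Scans all antiparallel ungapped offsets of the two oligomers for the
#' longest perfectly complementary run at each offset, and returns the most
#' negative duplex energy over those runs. Runs shorter than `min_run`
#' consecutive pairs are considered no interaction.
#'
#' @param oligo_a,oligo_b RNA strings.
#' @param params [nn_params()].
#' @param min_run Minimum run length (pairs) to report.
#' @return Energy in kcal/mol, or `NA` if no run of `min_run` or more.
#' @export
cross_hybridization <- function(oligo_a, oligo_b, params = nn_params(),
                                min_run = 4) {
  a <- seq_chars(as_rna(oligo_a, "oligo_a"))
  b <- seq_chars(as_rna(oligo_b, "oligo_b"))
  na <- length(a); nb <- length(b)
  best <- NA_real_
  # antiparallel register: a[i] pairs b[j] with i + j = const
  for (const in 2L:(na + nb)) {
    run <- 0L
    lo <- max(1L, const - nb)
    hi <- min(na, const - 1L)
    if (lo > hi) next
    for (i in lo:hi) {
      j <- const - i
      if (WC_PARTNER[a[i]] == b[j]) {
        run <- run + 1L
        if (run >= min_run) {
          sub <- paste(a[(i - run + 1L):i], collapse = "")
          dg <- duplex_energy(sub, rna_revcomp(sub), params)$dg37
          if (is.na(best) || dg < best) best <- dg
        }
      } else run <- 0L
    }
  }
  best
}
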