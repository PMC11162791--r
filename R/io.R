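#' Read a multi-FASTA file into a tibble
#'
#' @param path FASTA file.
#' @param as_rna Convert T to U and validate the alphabet.
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path, as_rna = TRUE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  if (as_rna) seqs <- suppressWarnings(as_rna(seqs, what = basename(path)))
  tibble::tibble(id = ids, seq = unname(seqs))
}

#' Write sequences to a multi-FASTA file (wrapped at 60 columns)
#'
#' @param x Tibble with `id` and `seq`, or a named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) x <- stats::setNames(x$seq, x$id)
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read mature-arm annotations from a 5-column TSV
#'
#' File columns (1-based inclusive coordinates, as annotations are usually
#' distributed): `name`, `arm5p_start`, `arm5p_end`, `arm3p_start`,
#' `arm3p_end`. Converted to the package's internal 0-based half-open
#' intervals.
#'
#' @param path TSV file.
#' @return Tibble with `name` and interval list-columns `arm5p`, `arm3p`.
#' @export
read_arms_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("name", "arm5p_start", "arm5p_end", "arm3p_start", "arm3p_end")
  if (!all(need %in% names(tab))) {
    stop(sprintf("arms TSV needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  tibble::tibble(
    name = tab$name,
    arm5p = purrr::map2(tab$arm5p_start, tab$arm5p_end,
                        ~interval(.x - 1L, .y)),
    arm3p = purrr::map2(tab$arm3p_start, tab$arm3p_end,
                        ~interval(.x - 1L, .y)))
}

#' Write an arms TSV (1-based inclusive)
#'
#' @param hairpins List of `premirna_hairpin` records.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_arms_tsv <- function(hairpins, path) {
  tab <- dplyr::bind_rows(lapply(hairpins, function(h) {
    tibble::tibble(name = h$name,
                   arm5p_start = h$arm5p$start + 1L, arm5p_end = h$arm5p$end,
                   arm3p_start = h$arm3p$start + 1L, arm3p_end = h$arm3p$end)
  }))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a dot-bracket companion file
#'
#' Format: one `>name` line followed by one dot-bracket line per record
#' (the ".db" companion of a FASTA file).
#'
#' @param path File path.
#' @return Named character vector of structures.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no '>' headers found in dot-bracket file", call. = FALSE)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  vals <- lines[!hdr]
  if (length(ids) != length(vals)) {
    stop("dot-bracket file must have exactly one structure line per header",
         call. = FALSE)
  }
  stats::setNames(vals, ids)
}

#' Write a dot-bracket companion file
#'
#' @param structures Named character vector of dot-bracket strings.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(structures, path) {
  writeLines(as.vector(rbind(paste0(">", names(structures)),
                             unname(structures))), path)
  invisible(path)
}

#' Load annotated hairpins from FASTA + arms TSV (+ optional structures)
#'
#' @param fasta Multi-FASTA of precursor sequences.
#' @param arms Arms TSV (see [read_arms_tsv()]).
#' @param dotbracket Optional ".db" companion file.
#' @return Named list of `premirna_hairpin` records.
#' @export
read_hairpins <- function(fasta, arms, dotbracket = NULL) {
  seqs <- read_fasta(fasta)
  ann <- read_arms_tsv(arms)
  db <- if (!is.null(dotbracket)) read_dotbracket(dotbracket) else NULL
  missing_ann <- setdiff(seqs$id, ann$name)
  if (length(missing_ann) > 0) {
    stop(sprintf("no arm annotation for: %s", paste(missing_ann, collapse = ", ")),
         call. = FALSE)
  }
  hps <- lapply(seq_len(nrow(seqs)), function(i) {
    a <- ann[ann$name == seqs$id[i], ]
    parse_hairpin(seqs$seq[i], a$arm5p[[1]], a$arm3p[[1]], name = seqs$id[i],
                  structure = if (!is.null(db) && seqs$id[i] %in% names(db))
                    db[[seqs$id[i]]] else NULL)
  })
  stats::setNames(hps, seqs$id)
}
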