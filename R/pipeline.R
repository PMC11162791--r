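#' Read a flat key=value configuration file
#'
#' INI-style sections (`[design]`, `[control]`) become name prefixes
#' (`design.k`); blank lines and `#` comments are ignored. The raw lines
#' are kept and echoed into report headers for provenance.
#'
#' @param path Config file.
#' @return Named list of character values, with attribute `"raw"`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  keep <- trimws(lines)
  keep <- keep[nzchar(keep) & !startsWith(keep, "#")]
  section <- ""
  out <- list()
  for (ln in keep) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("config line is not key=value: '%s'", ln), call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    nm <- if (nzchar(section)) paste(section, key, sep = ".") else key
    out[[nm]] <- val
  }
  attr(out, "raw") <- lines
  out
}

pipeline_log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), level,
                  sprintf(fmt, ...)))
}

#' End-to-end design (and optional control) pipeline
#'
#' Wires the whole workflow: hairpin parsing, candidate enumeration,
#' scoring against a reference index and the sibling precursors, ranking,
#' and (when a `[control]` section is present) the negative-control
#' pipeline. Reports are written as TSV plus a JSON trace; the config is
#' echoed into the JSON for provenance. Missing inputs are enumerated in
#' one pass before any compute.
#'
#' Config keys: `premirna` (FASTA), `arms` (TSV), `structure` (optional
#' .db), `reference` (FASTA), `seed`; section `[design]`: `k`, `loop_flank`,
#' `min_side`, `threshold`; section `[control]` (optional): `k`,
#' `v_schedule` (comma-separated), `n`; `out_prefix` for output paths.
#'
#' @param config Path to a config file, or a list from [read_config()].
#' @param dry_run Validate the configuration and inputs, touch no outputs.
#' @return List: `designs` (named list of `ranked_design`), `controls`
#'   (`control_pool` or NULL), `outputs` (paths written). Errors if every
#'   design comes back empty.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else config
  need <- c("premirna", "arms", "reference", "seed")
  missing_keys <- setdiff(need, names(cfg))
  files <- unlist(cfg[intersect(c("premirna", "arms", "structure", "reference"),
                                names(cfg))])
  missing_files <- if (length(files)) files[!file.exists(files)] else character()
  problems <- c(
    if (length(missing_keys)) sprintf("missing config keys: %s",
                                      paste(missing_keys, collapse = ", ")),
    if (length(missing_files)) sprintf("missing input files: %s",
                                       paste(missing_files, collapse = ", ")))
  if (length(problems) > 0) stop(paste(problems, collapse = "; "), call. = FALSE)
  if (dry_run) {
    pipeline_log("INFO", "dry run: configuration valid")
    return(invisible(list(designs = NULL, controls = NULL, outputs = character())))
  }
  num <- function(key, default) {
    if (key %in% names(cfg)) as.numeric(cfg[[key]]) else default
  }
  pipeline_log("INFO", "loading inputs")
  hairpins <- read_hairpins(cfg$premirna, cfg$arms,
                            dotbracket = cfg[["structure"]])
  ref <- read_fasta(cfg$reference)
  params <- nn_params()
  k <- as.integer(num("design.k", 13))
  pipeline_log("INFO", "indexing reference (%d transcript(s), k = %d)",
               nrow(ref), k)
  index <- build_index(ref, k = k)
  designs <- lapply(names(hairpins), function(nm) {
    sibs <- vapply(hairpins[setdiff(names(hairpins), nm)],
                   function(h) h$sequence, character(1))
    pipeline_log("INFO", "designing against %s", nm)
    design_asos(hairpins[[nm]], params = params, index = index,
                paralogs = sibs, k = k,
                loop_flank = num("design.loop_flank", 1),
                min_side = num("design.min_side", 2),
                threshold = num("design.threshold", 2))
  })
  names(designs) <- names(hairpins)
  if (all(vapply(designs, nrow, integer(1)) == 0L)) {
    stop("pipeline produced no ranked candidate for any precursor", call. = FALSE)
  }
  controls <- NULL
  if (any(startsWith(names(cfg), "control."))) {
    ck <- as.integer(num("control.k", 13))
    vs <- as.integer(strsplit(
      if ("control.v_schedule" %in% names(cfg)) cfg$`control.v_schedule`
      else "0,1,2", ",")[[1]])
    cindex <- if (ck == k) index else build_index(ref, k = ck)
    pipeline_log("INFO", "running control pipeline (k = %d)", ck)
    controls <- design_controls(cindex, k = ck, v_schedule = vs,
                                n = as.integer(num("control.n", 1)),
                                seed = as.integer(num("seed", 1)),
                                params = params)
  }
  outputs <- character()
  if ("out_prefix" %in% names(cfg)) {
    outputs <- write_pipeline_reports(cfg, designs, controls)
  }
  invisible(list(designs = designs, controls = controls, outputs = outputs))
}

write_pipeline_reports <- function(cfg, designs, controls) {
  prefix <- cfg$out_prefix
  outputs <- character()
  for (nm in names(designs)) {
    path <- paste0(prefix, "_design_", nm, ".tsv")
    df <- tidy(designs[[nm]])
    df$lna_positions <- NULL
    readr::write_tsv(df, path)
    outputs <- c(outputs, path)
  }
  trace <- list(
    config = attr(cfg, "raw"),
    designs = lapply(designs, function(d) as.list(glance(d))),
    controls = if (!is.null(controls)) {
      list(trace = controls$trace, rejections = controls$rejections,
           controls = controls$controls[, c("name", "target_site", "modified")],
           seed = controls$seed)
    })
  jpath <- paste0(prefix, "_trace.json")
  jsonlite::write_json(trace, jpath, auto_unbox = TRUE, digits = NA, null = "null")
  outputs <- c(outputs, jpath)
  if (!is.null(controls)) {
    cpath <- paste0(prefix, "_controls.fasta")
    write_fasta(stats::setNames(controls$controls$sequence,
                                controls$controls$name), cpath)
    outputs <- c(outputs, cpath)
  }
  pipeline_log("INFO", "wrote %d output file(s)", length(outputs))
  outputs
}
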