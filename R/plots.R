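#' Plot a ranked design
#'
#' On-target duplex energy against single-mismatch off-target load, one
#' point per surviving candidate, coloured by candidate class; the
#' top-ranked oligomer is labelled. Stronger designs sit low and left.
#'
#' @param object A `ranked_design`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ranked_design <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) == 0) stop("nothing to plot: empty ranked design", call. = FALSE)
  if (!"hits_v1" %in% names(df) || all(is.na(df$hits_v1))) df$hits_v1 <- 0L
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hits_v1, y = .data$dg37,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(data = df[df$rank == 1, ],
                       ggplot2::aes(label = .data$sequence),
                       vjust = -1, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "off-target hits at 1 mismatch",
                  y = expression(Delta * G * degree[37] ~ "(kcal/mol)"),
                  colour = "class",
                  title = unique(df$precursor)) +
    ggplot2::theme_minimal()
}

#' Plot an elimination trace
#'
#' Survivor counts per mismatch-allowance round of the negative-control
#' pipeline, on a log10 scale.
#'
#' @param object A `control_pool` (or `elimination_result`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.control_pool <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = factor(.data$v),
                                   y = .data$survivor_count + 1)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mismatches allowed (v)", y = "survivors + 1 (log10)",
                  title = "candidate-site elimination") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.elimination_result <- autoplot.control_pool

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
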