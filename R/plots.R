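#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_line
#'   geom_hline labs scale_x_log10 theme_minimal
#' @export
ggplot2::autoplot

#' Volcano-style plot of an association table
#'
#' @param object An `assoc_tbl` (from [run_imewas()] or [dm_test()]).
#' @param fdr Highlighting threshold.
#' @param ... Unused.
#' @return A ggplot object: z score against -log10 p, significant units
#'   highlighted.
#' @export
autoplot.assoc_tbl <- function(object, fdr = 0.05, ...) {
  d <- filter(as_tibble(object), !is.na(.data$p))
  d$significant <- !is.na(d$fdr) & d$fdr < fdr
  ggplot(d, aes(x = .data$z, y = -log10(.data$p),
                colour = .data$significant)) +
    geom_point(alpha = 0.7) +
    labs(x = "z score", y = expression(-log[10](p)),
         colour = sprintf("FDR < %g", fdr),
         title = unique(d$analysis)[1]) +
    theme_minimal()
}

#' Plot the overlap cascade trace
#'
#' @param object An `enrich_cascade`.
#' @param ... Unused.
#' @return A ggplot: per-iteration -log10 binomial p with the significance
#'   threshold line.
#' @export
autoplot.enrich_cascade <- function(object, ...) {
  d <- mutate(object$trace,
              label = paste0("it", .data$iteration, ": ", .data$analysis))
  ggplot(d, aes(x = .data$label, y = -log10(.data$p_value),
                fill = .data$passed)) +
    geom_col() +
    geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    labs(x = NULL, y = expression(-log[10](p)),
         fill = "passed",
         title = sprintf("Overlap cascade (universe %d)",
                         object$universe_size)) +
    theme_minimal()
}

#' Plot a distance-window scan
#'
#' @param object A `window_scan`.
#' @param ... Unused.
#' @return A ggplot: DEG proportion against window size (log scale) with
#'   the genome-wide rate and the selected window marked.
#' @export
autoplot.window_scan <- function(object, ...) {
  d <- tidy.window_scan(object)
  ggplot(d, aes(x = .data$window, y = .data$proportion)) +
    geom_line() +
    geom_point(aes(colour = .data$selected), size = 2) +
    geom_hline(yintercept = object$null_rate, linetype = 2) +
    scale_x_log10() +
    labs(x = "window half-width (bp)", y = "DEG proportion",
         colour = "selected",
         title = sprintf("Selected window: %g bp", object$selected_window)) +
    theme_minimal()
}
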