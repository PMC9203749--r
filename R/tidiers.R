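#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the iteration trace of an overlap cascade
#'
#' @param x An `enrich_cascade`.
#' @param ... Unused.
#' @return The per-iteration trace tibble.
#' @export
tidy.enrich_cascade <- function(x, ...) x$trace

#' One-row summary of an overlap cascade
#'
#' @param x An `enrich_cascade`.
#' @param ... Unused.
#' @return Tibble with `n_iterations`, `n_enriched`, `universe_size`,
#'   `halted`, `min_p`.
#' @export
glance.enrich_cascade <- function(x, ...) {
  tibble(n_iterations = nrow(x$trace),
         n_enriched = length(x$enriched),
         universe_size = x$universe_size,
         halted = x$halted,
         min_p = if (nrow(x$trace)) min(x$trace$p_value) else NA_real_)
}

#' Tidy the selected SNPs of a conditional scan
#'
#' @param x A `cond_scan`.
#' @param ... Unused.
#' @return Tibble of selected SNPs with entry and joint statistics.
#' @export
tidy.cond_scan <- function(x, ...) x$selected

#' One-row summary of a conditional scan
#'
#' @param x A `cond_scan`.
#' @param ... Unused.
#' @return Tibble with `n_selected`, `n_skipped`, `termination`.
#' @export
glance.cond_scan <- function(x, ...) {
  tibble(n_selected = nrow(x$selected),
         n_skipped = length(x$skipped),
         termination = x$termination)
}

#' Tidy a distance-window scan
#'
#' @param x A `window_scan`.
#' @param ... Unused.
#' @return Per-window tibble with a `selected` flag.
#' @export
tidy.window_scan <- function(x, ...) {
  mutate(x$scan, selected = .data$window == x$selected_window)
}

#' One-row summary of a distance-window scan
#'
#' @param x A `window_scan`.
#' @param ... Unused.
#' @return Tibble with `selected_window`, `n_selected_genes`, `null_rate`.
#' @export
glance.window_scan <- function(x, ...) {
  tibble(selected_window = x$selected_window,
         n_selected_genes = length(x$selected_genes),
         null_rate = x$null_rate)
}
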