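#' Exact binomial enrichment test
#'
#' Exact binomial tail probability of `k` successes in `n` trials against
#' null proportion `p0`. One-sided tails are exact sums; the two-sided
#' p-value uses the point-probability-summation convention (sum of all
#' outcome probabilities not exceeding that of the observed count, with
#' relative tolerance 1e-7), as implemented by `stats::binom.test`.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials.
#' @param p0 Null proportion in (0, 1).
#' @param side `"greater"`, `"less"` or `"two.sided"`.
#' @param alpha Significance level for the `enriched` flag.
#' @return One-row tibble of class `enrich_result`: `k`, `n`, `p0`,
#'   `observed` (k/n), `side`, `p_value`, `enriched` (p < alpha and
#'   observed above/below p0 as appropriate).
#' @export
binom_enrich <- function(k, n, p0, side = c("greater", "less", "two.sided"),
                         alpha = 0.05) {
  side <- match.arg(side)
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie in (0, 1).")
  stopifnot(k >= 0, k <= n, n >= 1)
  p_value <- binom.test(k, n, p0, alternative = side)$p.value
  out <- tibble(k = as.integer(k), n = as.integer(n), p0 = p0,
                observed = k / n, side = side, p_value = p_value,
                enriched = p_value < alpha)
  class(out) <- c("enrich_result", class(out))
  out
}

dm_set <- function(assoc, fdr = 0.05) {
  assoc$unit_id[!is.na(assoc$fdr) & assoc$fdr < fdr]
}

#' Stepwise overlap-enrichment cascade
#'
#' Starting from the discovery (imputation) significant set, iteratively
#' intersects with the significant set of each further analysis. At
#' iteration j the overlap of the current set with analysis j's DM set is
#' tested by a one-sided (greater) exact binomial with `n` = current-set
#' size and null proportion = analysis j's DM rate over the shared tested
#' universe. The cascade proceeds only while p < `alpha`; the surviving
#' overlap is the enriched CpG set. With a single further analysis exactly
#' one iteration runs.
#'
#' @param primary Discovery `assoc_tbl` (e.g. the imputation scan).
#' @param others Ordered list of further `assoc_tbl`s (e.g. tumour-healthy
#'   then tumour-NAT differential methylation). Order matters and is
#'   recorded in the trace.
#' @param fdr FDR threshold defining each analysis's DM set.
#' @param alpha Per-iteration binomial significance threshold (strict:
#'   the cascade proceeds only if p < alpha).
#' @param sets Optional list: pre-selected unit sets overriding the
#'   FDR rule (used by [directional_enrichment()]).
#' @param universe Optional character vector overriding the tested-unit
#'   universe (default: intersection of the tables' tested units).
#' @return Object of class `enrich_cascade`: list with `enriched`
#'   (character vector, empty if any iteration fails), `trace` (tibble:
#'   one row per iteration with k, n, p0, p_value, passed), `universe_size`.
#' @export
stepwise_enrichment <- function(primary, others, fdr = 0.05, alpha = 0.05,
                                sets = NULL, universe = NULL) {
  if (inherits(others, "data.frame")) others <- list(others)
  tables <- c(list(primary), others)
  if (is.null(universe)) {
    universe <- Reduce(intersect, lapply(tables, function(t) t$unit_id))
  }
  if (!length(universe)) abort("Empty tested-CpG universe.")
  if (is.null(sets)) {
    sets <- lapply(tables, dm_set, fdr = fdr)
  }
  sets <- lapply(sets, intersect, y = universe)
  current <- sets[[1]]
  trace <- list()
  halted <- FALSE
  for (j in seq_along(others)) {
    other <- sets[[j + 1]]
    k <- length(intersect(current, other))
    n <- length(current)
    p0 <- length(other) / length(universe)
    p_value <- if (n == 0 || p0 <= 0 || p0 >= 1) {
      1
    } else {
      binom.test(k, n, p0, alternative = "greater")$p.value
    }
    passed <- p_value < alpha
    trace[[j]] <- tibble(iteration = j,
                         analysis = others[[j]]$analysis[1] %||% paste0("a", j),
                         n_current = n, n_other = length(other),
                         k_overlap = k, p0 = p0, p_value = p_value,
                         passed = passed)
    if (!passed) {
      current <- character(0)
      halted <- TRUE
      break
    }
    current <- intersect(current, other)
  }
  structure(list(enriched = current, trace = bind_rows(trace),
                 universe_size = length(universe), halted = halted,
                 alpha = alpha),
            class = "enrich_cascade")
}

#' @export
print.enrich_cascade <- function(x, ...) {
  cat(sprintf("<enrich_cascade> universe %d, %d iteration(s), %s\n",
              x$universe_size, nrow(x$trace),
              if (x$halted) "halted" else
                sprintf("enriched set of %d", length(x$enriched))))
  print(x$trace)
  invisible(x)
}

#' Directional (hypo / hyper) overlap cascade
#'
#' Selects, per analysis, the nominally significant units (uncorrected
#' p < `p_nominal`) whose z sign matches the requested direction
#' (z < 0 is hypomethylated) and runs the overlap cascade on those sets.
#'
#' @param primary,others As in [stepwise_enrichment()].
#' @param direction `"hypo"` or `"hyper"`.
#' @param p_nominal Uncorrected p threshold for set membership.
#' @param alpha Cascade significance threshold.
#' @return An `enrich_cascade`.
#' @export
directional_enrichment <- function(primary, others, direction = c("hypo", "hyper"),
                                   p_nominal = 0.05, alpha = 0.05) {
  direction <- match.arg(direction)
  if (inherits(others, "data.frame")) others <- list(others)
  tables <- c(list(primary), others)
  sel <- lapply(tables, function(t) {
    keep <- !is.na(t$p) & t$p < p_nominal &
      (if (direction == "hypo") t$z < 0 else t$z > 0)
    t$unit_id[keep]
  })
  stepwise_enrichment(primary, others, alpha = alpha, sets = sel)
}

#' Annotation-category enrichment of a CpG set
#'
#' For each annotation category (and optional unions of categories), tests
#' whether the CpG set's category proportion differs from the background
#' proportion among the tested universe, using the two-sided exact binomial
#' (point-probability convention). Enrichment versus depletion is read off
#' the sign of `observed - p0`.
#'
#' @param cpg_set Character vector of CpG ids.
#' @param categories Tibble with `cpg_id` and `category` for the whole
#'   background universe.
#' @param unions Optional named list of character vectors; each entry
#'   tests the union of those categories (e.g.
#'   `list("UTR5+intronic+UTR3" = c("UTR5", "intronic", "UTR3"))`).
#' @param alpha Significance level for flags.
#' @return Tibble with one row per category / union: `category`, `k`, `n`,
#'   `p0`, `observed`, `p_value`, `effect` ("enrichment" / "depletion").
#' @export
annotation_enrichment <- function(cpg_set, categories, unions = NULL,
                                  alpha = 0.05) {
  categories <- as_tibble(categories)
  if (!all(cpg_set %in% categories$cpg_id)) {
    abort("Every CpG in the set must be categorised.")
  }
  n <- length(cpg_set)
  in_set <- categories$cpg_id %in% cpg_set
  tests <- c(as.list(setNames(unique(categories$category),
                              unique(categories$category))),
             unions)
  rows <- purrr::imap(tests, function(cats, label) {
    bg <- categories$category %in% cats
    p0 <- mean(bg)
    if (p0 <= 0 || p0 >= 1) {
      warn(sprintf("Category %s absent from (or covering all of) background; skipped.",
                   label))
      return(NULL)
    }
    k <- sum(bg & in_set)
    res <- binom_enrich(k, n, p0, side = "two.sided", alpha = alpha)
    tibble(category = label, k = res$k, n = res$n, p0 = p0,
           observed = res$observed, p_value = res$p_value,
           effect = ifelse(res$observed >= p0, "enrichment", "depletion"),
           significant = res$p_value < alpha)
  })
  bind_rows(purrr::compact(rows))
}
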