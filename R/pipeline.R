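#' Run the full discovery - overlap - characterisation pipeline
#'
#' Convenience wrapper chaining the three steps on a (simulated or loaded)
#' study: the imputation scan on GWAS summary statistics, QC + outlier
#' removal + differential methylation for the tumour/healthy and
#' tumour/NAT contrasts, the stepwise overlap cascade, and (optionally)
#' the characterisation analyses on the enriched set (annotation
#' categories, differential expression, window scan, mediation, region
#' classification, LD-block assignment).
#'
#' @param study A `sim_study` (or a list with the same elements: `gwas`,
#'   `weights`, `panel`, `meth`, `expr`, `annotation`).
#' @param fdr FDR threshold shared by all discovery analyses.
#' @param alpha Cascade binomial threshold.
#' @param n_pcs Principal-component covariates in the tissue regressions
#'   (default 2, matching the two structured nuisance axes - batch and age -
#'   present in the synthetic studies; scale up for array-scale data).
#' @param contrasts Which tissue contrasts feed the cascade: both
#'   `"th"` (tumour vs healthy) and `"tn"` (tumour vs NAT), or `"tn"`
#'   alone when no healthy group exists.
#' @param characterise Run the characterisation step (default TRUE).
#' @return List of class `methlink_run`: `imewas`, `th_dm`, `tn_dm`,
#'   `cascade`, `enriched` (CpG ids) and, when characterised,
#'   `annotation_enrichment`, `de`, `window_scan`, `mediation`,
#'   `concordance`, `region_class`, `ld_blocks`.
#' @export
run_pipeline <- function(study, fdr = 0.05, alpha = 0.05, n_pcs = 2,
                         contrasts = c("th", "tn"), characterise = TRUE) {
  imewas <- run_imewas(study$weights, study$gwas, study$panel, fdr = fdr)

  qc <- qc_and_impute(study$meth)
  clean <- pc1_outlier_removal(qc)$mat
  others <- list()
  th_dm <- tn_dm <- NULL
  if ("th" %in% contrasts) {
    th_dm <- dm_test(clean, case = "tumour", control = "healthy",
                     n_pcs = n_pcs, analysis_tag = "th_dm")
    others <- c(others, list(th_dm))
  }
  if ("tn" %in% contrasts) {
    tn_dm <- dm_test(clean, case = "tumour", control = "NAT",
                     n_pcs = n_pcs, analysis_tag = "tn_dm")
    others <- c(others, list(tn_dm))
  }
  cascade <- stepwise_enrichment(imewas, others, fdr = fdr, alpha = alpha)
  out <- list(imewas = imewas, th_dm = th_dm, tn_dm = tn_dm,
              cascade = cascade, enriched = cascade$enriched)

  if (characterise && length(cascade$enriched)) {
    ann <- study$annotation
    cpg_pos <- filter(ann$cpgs, .data$cpg_id %in% cascade$enriched)
    anno <- annotate_cpgs(ann$cpgs, ann)
    out$annotation_enrichment <- annotation_enrichment(
      cascade$enriched,
      select(anno, "cpg_id", "category"),
      unions = list("UTR5+intronic+UTR3" = c("UTR5", "intronic", "UTR3")))
    out$de <- de_test(study$expr)
    out$window_scan <- distance_window_scan(cpg_pos, out$de, ann$genes)
    pairs <- anno %>%
      filter(.data$cpg_id %in% cascade$enriched, !is.na(.data$genes)) %>%
      tidyr::separate_rows("genes", sep = ",") %>%
      select("cpg_id", gene_id = "genes")
    if (nrow(pairs)) {
      out$mediation <- mediation_test(study$expr, clean, pairs)
      dm_for_pairs <- if (!is.null(tn_dm)) tn_dm else th_dm
      out$concordance <- direction_concordance(dm_for_pairs, out$de, pairs)
    }
    out$region_class <- classify_region(cpg_pos, study$gwas)
    out$ld_blocks <- ld_block_assign(cpg_pos, ann$blocks)
  }
  structure(out, class = "methlink_run")
}

#' @export
print.methlink_run <- function(x, ...) {
  cat("<methlink_run>\n")
  cat(sprintf("  discovery: %d imputed, %s tested tissue contrast(s)\n",
              nrow(x$imewas),
              sum(!vapply(list(x$th_dm, x$tn_dm), is.null, logical(1)))))
  cat(sprintf("  enriched CpGs: %d\n", length(x$enriched)))
  invisible(x)
}
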