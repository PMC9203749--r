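#' Empirical LD matrix from a reference panel
#'
#' Computes the empirical covariance (denominator n - 1) and correlation of
#' the dosage columns for a set of SNPs, preserving the requested order.
#'
#' @param panel A `ref_panel`.
#' @param snp_ids Character vector of SNP ids, all present in the panel.
#' @return List of class `ld_matrix` with elements `snp_ids`, `sigma`
#'   (covariance), `corr` (correlation) and `sd` (per-SNP dosage sd).
#' @export
ld_matrix <- function(panel, snp_ids) {
  missing <- setdiff(snp_ids, panel$snps$snp_id)
  if (length(missing)) {
    abort(paste0("SNP(s) absent from panel: ",
                 paste(missing, collapse = ", ")))
  }
  d <- panel$dosage[, snp_ids, drop = FALSE]
  sigma <- stats::cov(d)
  sds <- sqrt(diag(sigma))
  corr <- sigma / tcrossprod(sds)
  structure(list(snp_ids = snp_ids, sigma = sigma, corr = corr, sd = sds),
            class = "ld_matrix")
}

#' Imputed differential-methylation Z score for one weight model
#'
#' The summary-statistics association statistic for a genetically predicted
#' molecular trait: with SNP weights `w_l`, reference-panel dosage
#' standard deviations `sigma_l`, GWAS per-SNP Wald ratios `beta_l / se_l`
#' and predicted-trait sd `sigma_g = sqrt(w' Sigma w)`,
#'
#' \deqn{Z = \sum_l w_l \frac{\sigma_l}{\sigma_g} \frac{\beta_l}{se_l}.}
#'
#' Model SNPs absent from the GWAS are dropped (partial-model imputation)
#' and the retained fraction reported; a model with no remaining SNPs or
#' with `sigma_g` below tolerance is untestable and returns `NULL`.
#'
#' @param model One unit's rows of a `weight_tbl` (harmonized frame).
#' @param gwas Harmonized `gwas_tbl`.
#' @param ld An `ld_matrix` covering the model SNPs.
#' @param tol Minimum `sigma_g`; below it the model is skipped.
#' @return One-row tibble (`unit_id`, `z`, `p`, `sigma_g`, `n_snps_used`,
#'   `coverage`, `direction`) or `NULL` for an untestable model.
#' @export
mewas_z <- function(model, gwas, ld, tol = 1e-8) {
  m <- model[model$snp_id %in% gwas$snp_id, , drop = FALSE]
  coverage <- nrow(m) / nrow(model)
  if (nrow(m) < 1) return(NULL)
  gi <- match(m$snp_id, gwas$snp_id)
  li <- match(m$snp_id, ld$snp_ids)
  if (anyNA(li)) abort("LD matrix does not cover all model SNPs.")
  w <- m$weight
  sig <- ld$sigma[li, li, drop = FALSE]
  sigma_g <- sqrt(max(drop(t(w) %*% sig %*% w), 0))
  if (sigma_g <= tol) {
    inform(sprintf("Unit %s: sigma_g ~ 0, untestable model skipped.",
                   m$unit_id[1]))
    return(NULL)
  }
  z <- sum(w * ld$sd[li] / sigma_g * gwas$beta[gi] / gwas$se[gi])
  tibble(unit_id = m$unit_id[1], z = z,
         p = 2 * pnorm(-abs(z)),
         sigma_g = sigma_g, n_snps_used = nrow(m), coverage = coverage,
         direction = ifelse(z < 0, "hypo", "hyper"))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: p-values
#' must lie in (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted values (monotone step-up, all <= 1).
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Run the imputation-based methylome-wide association scan
#'
#' Harmonizes all inputs to the panel allele frame, computes [mewas_z()]
#' for every weight model and applies Benjamini-Hochberg FDR over the
#' tested units. Units with FDR < `fdr` form the significant set.
#'
#' @param weights A `weight_tbl` (one or many units).
#' @param gwas A `gwas_tbl`.
#' @param panel A `ref_panel`.
#' @param fdr Significance threshold on the adjusted p-value.
#' @param harmonize Rotate alleles onto the panel frame first (set `FALSE`
#'   if the inputs are already harmonized).
#' @param analysis_tag Label recorded in the `analysis` column (default
#'   `"imewas"`; use `"eqtl_de"` when the weights are expression models).
#' @return An association tibble of class `assoc_tbl`: `unit_id`, `z`,
#'   `p`, `fdr`, `direction`, `sigma_g`, `n_snps_used`, `coverage`,
#'   `significant`, `analysis`.
#' @export
run_imewas <- function(weights, gwas, panel, fdr = 0.05, harmonize = TRUE,
                       analysis_tag = "imewas") {
  if (harmonize) {
    h <- harmonize_alleles(gwas, weights, panel)
    gwas <- h$gwas; weights <- h$weights; panel <- h$panel
  }
  units <- split(weights, weights$unit_id)
  ld <- ld_matrix(panel, intersect(unique(weights$snp_id), panel$snps$snp_id))
  rows <- purrr::compact(purrr::map(units, mewas_z, gwas = gwas, ld = ld))
  if (!length(rows)) abort("No testable weight model.")
  thr <- fdr
  out <- bind_rows(rows) %>%
    mutate(fdr = bh_fdr(.data$p),
           significant = .data$fdr < thr,
           analysis = analysis_tag) %>%
    arrange(.data$p)
  class(out) <- c("assoc_tbl", class(out))
  out
}
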