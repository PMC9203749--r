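#' Familial-relative-risk contribution of a SNP set
#'
#' Under the log-additive model, the proportion of the familial relative
#' risk `lambda` explained by SNPs with minor allele frequency `p_i`,
#' log-odds effect `beta_i` and standard error `tau_i` is
#' \deqn{\sum_i p_i (1 - p_i) (\beta_i^2 - \tau_i^2) / \ln \lambda.}
#' The formula is applied exactly as written (no factor 2 in
#' `p (1 - p)`); set `factor2 = TRUE` for the conventional `2 p (1 - p)`
#' variance term. Negative per-SNP terms (when `tau_i > |beta_i|`) are
#' retained, not floored.
#'
#' @param gwas Rows of a `gwas_tbl` for the SNP set (`eaf`, `beta`, `se`).
#' @param lambda Overall familial relative risk, > 1 (2 for breast cancer,
#'   2.5 for prostate cancer).
#' @param factor2 Use the conventional `2 p (1 - p)` term (default FALSE).
#' @return The summed proportion (scalar).
#' @export
frr_contribution <- function(gwas, lambda, factor2 = FALSE) {
  if (lambda <= 1) abort("lambda must exceed 1.")
  maf <- pmin(gwas$eaf, 1 - gwas$eaf)
  fac <- if (factor2) 2 else 1
  sum(fac * maf * (1 - maf) * (gwas$beta^2 - gwas$se^2)) / log(lambda)
}

#' Squared LD between two panel SNPs
#'
#' @param panel A `ref_panel`.
#' @param snp_a,snp_b SNP ids present in the panel.
#' @return Squared sample correlation of the dosage columns.
#' @export
ld_r2 <- function(panel, snp_a, snp_b) {
  miss <- setdiff(c(snp_a, snp_b), panel$snps$snp_id)
  if (length(miss)) abort(paste0("SNP(s) absent from panel: ",
                                 paste(miss, collapse = ", ")))
  a <- panel$dosage[, snp_a]
  b <- panel$dosage[, snp_b]
  if (sd(a) == 0 || sd(b) == 0) abort("Zero-variance SNP in ld_r2.")
  cor(a, b)^2
}

#' Classify the GWAS signal of a CpG's flanking region
#'
#' The minimum GWAS p-value among SNPs within `flank` bp of the CpG
#' decides: `genome_wide_significant` if min p <= 5e-8, `suggestive` if
#' 5e-8 < min p <= 1e-5, otherwise `novel`. A window with no SNP is
#' classified `novel` with a warning.
#'
#' @param cpgs Tibble with `cpg_id`, `chrom`, `pos`.
#' @param gwas A `gwas_tbl`.
#' @param flank Half-window in bp (default 1 Mb).
#' @param gws_p,suggestive_p Class boundaries.
#' @return Tibble: `cpg_id`, `min_p`, `region_class`.
#' @export
classify_region <- function(cpgs, gwas, flank = 1e6,
                            gws_p = 5e-8, suggestive_p = 1e-5) {
  purrr::map(seq_len(nrow(cpgs)), function(i) {
    cp <- cpgs[i, ]
    inwin <- gwas$chrom == cp$chrom & abs(gwas$pos - cp$pos) <= flank
    if (!any(inwin)) {
      warn(sprintf("CpG %s: no SNP within the window; classified novel.",
                   cp$cpg_id))
      return(tibble(cpg_id = cp$cpg_id, min_p = NA_real_,
                    region_class = "novel"))
    }
    mp <- min(gwas$p[inwin])
    tibble(cpg_id = cp$cpg_id, min_p = mp,
           region_class = case_when(mp <= gws_p ~ "genome_wide_significant",
                                    mp <= suggestive_p ~ "suggestive",
                                    TRUE ~ "novel"))
  }) %>% bind_rows()
}

# Summary-level joint regression via reconstructed normal equations:
# X'X ~ n * S R S with S = diag(sqrt(2 p (1-p))), X'y from marginal betas,
# phenotypic variance fixed at 1. Returns joint coefficients, their SEs
# (residual variance = 1 - explained fraction, floored) and z/p.
joint_from_summary <- function(ids, gwas, corr, freqs, n, var_floor = 0.1) {
  gi <- match(ids, gwas$snp_id)
  p <- freqs[ids]
  d <- 2 * p * (1 - p)
  s <- sqrt(d)
  R <- corr[ids, ids, drop = FALSE]
  XtX <- n * (s %o% s) * R
  Xty <- n * d * gwas$beta[gi]
  XtXinv <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(XtXinv)) return(NULL)
  b <- drop(XtXinv %*% Xty)
  explained <- sum(b * Xty) / n
  sigma2 <- max(1 - explained, var_floor)
  se <- sqrt(sigma2 * diag(XtXinv))
  z <- b / se
  tibble(snp_id = ids, beta_joint = b, se_joint = se, z = z,
         p_cond = 2 * pnorm(-abs(z)))
}

#' Iterative approximate conditional scan of meQTL SNPs
#'
#' Selects the meQTL SNP with the smallest marginal GWAS p below
#' `p_entry`, then iteratively computes each remaining candidate's
#' conditional p given the selected set — by summary-level least squares
#' reconstructed from marginal effects, per-SNP variances `2 p (1 - p)`
#' and panel LD, with phenotypic variance 1 and the residual variance
#' updated (1 - explained fraction, floored at 0.1) — and admits the
#' lowest conditional p while it stays below `p_entry`. Candidates with
#' `r^2 >` `r2_cap` to any selected SNP are never chosen; candidates that
#' make the normal equations singular are skipped and flagged.
#'
#' @param snp_ids Candidate meQTL SNP ids (a region's pooled SNPs; CpGs
#'   within 1 Mb of each other should be pooled before calling, see
#'   [pool_regions()]).
#' @param gwas Harmonized `gwas_tbl`.
#' @param panel Harmonized `ref_panel`.
#' @param p_entry Selection threshold (default 0.05).
#' @param r2_cap Collinearity guard (default 0.9).
#' @return Object of class `cond_scan`: list with `selected` (tibble:
#'   `snp_id`, `order`, `p_gwas`, `p_cond_entry`, plus the final joint
#'   statistics), `termination` (reason) and `skipped` (collinearity /
#'   singular flags).
#' @export
conditional_scan <- function(snp_ids, gwas, panel, p_entry = 0.05,
                             r2_cap = 0.9) {
  snp_ids <- intersect(unique(snp_ids), intersect(gwas$snp_id,
                                                  panel$snps$snp_id))
  if (!length(snp_ids)) {
    return(structure(list(selected = tibble(), termination = "no entry",
                          skipped = character(0)),
                     class = "cond_scan"))
  }
  ld <- ld_matrix(panel, snp_ids)
  corr <- ld$corr
  freqs <- setNames(panel$snps$freq[match(snp_ids, panel$snps$snp_id)],
                    snp_ids)
  n <- median(gwas$n[match(snp_ids, gwas$snp_id)])
  gi <- match(snp_ids, gwas$snp_id)
  marg_p <- setNames(gwas$p[gi], snp_ids)

  first <- names(which.min(marg_p))
  if (marg_p[first] >= p_entry) {
    return(structure(list(selected = tibble(), termination = "no entry",
                          skipped = character(0)),
                     class = "cond_scan"))
  }
  selected <- tibble(snp_id = first, order = 1L,
                     p_gwas = unname(marg_p[first]),
                     p_cond_entry = unname(marg_p[first]))
  skipped <- character(0)
  termination <- "exhausted candidates"
  repeat {
    remaining <- setdiff(snp_ids, c(selected$snp_id, skipped))
    if (!length(remaining)) break
    r2max <- apply(corr[remaining, selected$snp_id, drop = FALSE]^2, 1, max)
    eligible <- remaining[r2max <= r2_cap]
    if (!length(eligible)) {
      termination <- "all candidates collinear"
      break
    }
    cond <- purrr::map(eligible, function(cand) {
      fit <- joint_from_summary(c(selected$snp_id, cand), gwas, corr,
                                freqs, n)
      if (is.null(fit)) return(NULL)
      mutate(fit[fit$snp_id == cand, ], candidate = cand)
    })
    singular <- eligible[purrr::map_lgl(cond, is.null)]
    if (length(singular)) skipped <- c(skipped, singular)
    cond <- bind_rows(purrr::compact(cond))
    if (!nrow(cond) || min(cond$p_cond) >= p_entry) {
      termination <- "no further signal"
      break
    }
    best <- cond[which.min(cond$p_cond), ]
    selected <- bind_rows(selected,
                          tibble(snp_id = best$snp_id,
                                 order = nrow(selected) + 1L,
                                 p_gwas = unname(marg_p[best$snp_id]),
                                 p_cond_entry = best$p_cond))
  }
  final <- joint_from_summary(selected$snp_id, gwas, corr, freqs, n)
  if (!is.null(final)) {
    selected <- left_join(selected, final, by = "snp_id")
  }
  structure(list(selected = selected, termination = termination,
                 skipped = skipped, n = n),
            class = "cond_scan")
}

#' @export
print.cond_scan <- function(x, ...) {
  cat(sprintf("<cond_scan> %d SNP(s) selected (%s)\n",
              nrow(x$selected), x$termination))
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}

#' Pool CpGs into conditional-analysis regions
#'
#' Single-linkage merge: CpGs within `merge_window` of each other share a
#' region, and their meQTL SNPs are analysed together.
#'
#' @param cpgs Tibble with `cpg_id`, `chrom`, `pos`.
#' @param merge_window Merge distance in bp (default 1 Mb).
#' @return Input tibble with a `region_id` column.
#' @export
pool_regions <- function(cpgs, merge_window = 1e6) {
  cpgs <- arrange(cpgs, .data$chrom, .data$pos)
  new_region <- c(TRUE, diff(cpgs$pos) > merge_window |
                    cpgs$chrom[-1] != cpgs$chrom[-nrow(cpgs)])
  mutate(cpgs, region_id = paste0("region", cumsum(new_region)))
}

#' Inverse-variance fixed-effect meta-analysis with Cochran's Q
#'
#' Combines per-SNP effects across studies with weights `1 / se^2`:
#' combined beta `sum(w b) / sum(w)`, combined se `1 / sqrt(sum(w))`,
#' Cochran's Q `sum(w (b - b_comb)^2)` with `k - 1` degrees of freedom
#' (heterogeneity p reported as NA for a single study). Studies must share
#' a harmonized allele frame; SNPs whose effect alleles disagree across
#' studies are dropped and counted.
#'
#' @param studies List of `gwas_tbl`s.
#' @param het_p Threshold flagging heterogeneity (default 0.05).
#' @return Tibble of class `meta_tbl`: `snp_id`, `k_studies`, `beta`,
#'   `se`, `z`, `p`, `q`, `p_het`, `heterogeneous`. Attribute
#'   `n_dropped_alleles` counts irreconcilable SNPs.
#' @export
meta_fixed <- function(studies, het_p = 0.05) {
  if (!length(studies)) abort("Need at least one study.")
  long <- purrr::imap(studies, function(s, i) {
    mutate(select(as_tibble(s), "snp_id", "effect_allele", "other_allele",
                  "beta", "se"),
           study = i)
  }) %>% bind_rows()
  frames <- long %>%
    group_by(.data$snp_id) %>%
    summarise(ok = dplyr::n_distinct(paste(.data$effect_allele,
                                           .data$other_allele)) == 1,
              .groups = "drop")
  dropped <- sum(!frames$ok)
  if (dropped > 0) {
    warn(sprintf("Dropped %d SNP(s) with irreconcilable allele frames.",
                 dropped))
  }
  out <- long %>%
    semi_join(filter(frames, .data$ok), by = "snp_id") %>%
    group_by(.data$snp_id) %>%
    summarise(k_studies = dplyr::n(),
              beta_comb = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
              se_comb = 1 / sqrt(sum(1 / .data$se^2)),
              q = sum((.data$beta - beta_comb)^2 / .data$se^2),
              .groups = "drop") %>%
    rename(beta = "beta_comb", se = "se_comb") %>%
    mutate(z = .data$beta / .data$se,
           p = 2 * pnorm(-abs(.data$z)),
           p_het = ifelse(.data$k_studies > 1,
                          pchisq(.data$q, df = .data$k_studies - 1,
                                 lower.tail = FALSE),
                          NA_real_),
           heterogeneous = !is.na(.data$p_het) & .data$p_het < het_p)
  attr(out, "n_dropped_alleles") <- dropped
  class(out) <- c("meta_tbl", class(out))
  out
}

#' Pleiotropy link between two CpGs' meQTL SNP sets
#'
#' Two CpGs (for instance one per cancer) are linked when they share a
#' meQTL SNP or when any cross-pair of their meQTL SNPs is in at least
#' moderate LD (`r^2 > r2_thresh`).
#'
#' @param snps_a,snps_b Character vectors of meQTL SNP ids.
#' @param panel A `ref_panel` covering the SNPs.
#' @param r2_thresh LD threshold (default 0.4).
#' @return List: `linked` (logical), `shared` (shared SNP ids), `pairs`
#'   (tibble of qualifying cross pairs with their r2).
#' @export
pleiotropy_link <- function(snps_a, snps_b, panel, r2_thresh = 0.4) {
  if (!length(snps_a) || !length(snps_b)) {
    return(list(linked = FALSE, shared = character(0), pairs = tibble()))
  }
  shared <- intersect(snps_a, snps_b)
  grid <- tidyr::crossing(snp_a = setdiff(snps_a, shared),
                          snp_b = setdiff(snps_b, shared))
  pairs <- tibble()
  if (nrow(grid)) {
    grid$r2 <- purrr::map2_dbl(grid$snp_a, grid$snp_b, ld_r2, panel = panel)
    pairs <- filter(grid, .data$r2 > r2_thresh)
  }
  list(linked = length(shared) > 0 || nrow(pairs) > 0,
       shared = shared, pairs = pairs)
}

#' Assign CpGs to LD blocks
#'
#' Interval containment lookup against non-overlapping blocks; CpGs
#' outside every block are labelled `unassigned`.
#'
#' @param cpgs Tibble with `cpg_id`, `chrom`, `pos`.
#' @param blocks Tibble with `block_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return List: `assignment` (tibble `cpg_id`, `block_id`) and
#'   `occupancy` (tibble `block_id`, `n_cpgs`, assigned blocks only).
#' @export
ld_block_assign <- function(cpgs, blocks) {
  assignment <- purrr::map(seq_len(nrow(cpgs)), function(i) {
    cp <- cpgs[i, ]
    hit <- blocks$chrom == cp$chrom & blocks$start <= cp$pos &
      blocks$end >= cp$pos
    tibble(cpg_id = cp$cpg_id,
           block_id = if (any(hit)) blocks$block_id[which(hit)[1]]
                      else "unassigned")
  }) %>% bind_rows()
  occupancy <- assignment %>%
    filter(.data$block_id != "unassigned") %>%
    dplyr::count(.data$block_id, name = "n_cpgs")
  list(assignment = assignment, occupancy = occupancy)
}
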