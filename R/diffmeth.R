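#' Construct an omics matrix container
#'
#' @param values Feature-by-sample numeric matrix (beta values in \[0, 1\]
#'   for methylation, non-negative integer counts for expression). Row
#'   names are feature ids, column names sample ids.
#' @param meta Sample metadata with columns `sample_id`, `sample_type`
#'   (tumour / NAT / healthy) and `age`; must cover every column.
#' @return List of class `omics_mat`.
#' @export
omics_mat <- function(values, meta) {
  meta <- as_tibble(meta)
  stopifnot(!is.null(colnames(values)), !is.null(rownames(values)))
  if (!all(colnames(values) %in% meta$sample_id)) {
    abort("Metadata must cover every sample column.")
  }
  meta <- meta[match(colnames(values), meta$sample_id), ]
  structure(list(values = values, meta = meta), class = "omics_mat")
}

#' @export
print.omics_mat <- function(x, ...) {
  cat(sprintf("<omics_mat> %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$meta$sample_type)),
                            table(x$meta$sample_type)), collapse = ", ")))
  invisible(x)
}

#' Missingness QC and median imputation for methylation matrices
#'
#' Removes CpGs whose missing fraction exceeds `max_missing` in any sample
#' group (tumour, NAT, healthy evaluated separately), then fills the
#' remaining missing entries with the CpG's median across retained samples.
#'
#' @param mat An `omics_mat` of beta values.
#' @param max_missing Per-group missing-fraction threshold (default 0.10).
#' @return The filtered and imputed `omics_mat`; counts of removed CpGs
#'   and imputed entries attached as attribute `qc`.
#' @export
qc_and_impute <- function(mat, max_missing = 0.10) {
  v <- mat$values
  groups <- split(seq_len(ncol(v)), mat$meta$sample_type)
  frac <- matrix(vapply(groups, function(idx) {
    rowMeans(is.na(v[, idx, drop = FALSE]))
  }, numeric(nrow(v))), nrow = nrow(v))
  bad <- apply(frac, 1, max) > max_missing
  if (all(bad)) abort("All CpGs fail the missingness threshold.")
  v <- v[!bad, , drop = FALSE]
  n_imputed <- sum(is.na(v))
  if (n_imputed > 0) {
    med <- apply(v, 1, median, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- med[idx[, 1]]
  }
  out <- omics_mat(v, mat$meta)
  attr(out, "qc") <- list(n_removed = sum(bad), n_imputed = n_imputed)
  out
}

#' Remove PC1 outlier samples per group
#'
#' PCA on the centred beta matrix (samples as observations); within each
#' sample group, samples whose PC1 score lies outside
#' `[Q1 - whisker * IQR, Q3 + whisker * IQR]` (the box-plot whisker rule)
#' are removed. Removal is performed once, not iterated. Groups with fewer
#' than 4 samples are skipped with a warning.
#'
#' @param mat An `omics_mat` (post-QC, no missing values).
#' @param whisker Whisker multiplier (default 1.5).
#' @return List with `mat` (samples retained) and `removed` (character
#'   vector of dropped sample ids).
#' @export
pc1_outlier_removal <- function(mat, whisker = 1.5) {
  pc <- prcomp(t(mat$values), center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  removed <- character(0)
  for (g in unique(mat$meta$sample_type)) {
    idx <- which(mat$meta$sample_type == g)
    if (length(idx) < 4) {
      warn(sprintf("Group %s has %d sample(s); outlier screen skipped.",
                   g, length(idx)))
      next
    }
    q <- quantile(pc1[idx], c(0.25, 0.75))
    iqr <- q[2] - q[1]
    out <- pc1[idx] < q[1] - whisker * iqr | pc1[idx] > q[2] + whisker * iqr
    removed <- c(removed, mat$meta$sample_id[idx][out])
  }
  keep <- !mat$meta$sample_id %in% removed
  list(mat = omics_mat(mat$values[, keep, drop = FALSE],
                       mat$meta[keep, , drop = FALSE]),
       removed = removed)
}

#' Differential methylation regression
#'
#' Per CpG, fits the beta value on the ordinary-least-squares model
#' `beta ~ sample_type + age + age^2 + top K principal components`, where
#' the PCs are computed from the supplied (post-QC, post-outlier-removal)
#' matrix restricted to the two contrasted groups. The sample-type
#' coefficient's t statistic gives a signed z and two-sided p; BH FDR is
#' applied over the tested CpGs. CpGs with zero variance are reported as
#' NA rows and excluded from the FDR denominator.
#'
#' @param mat An `omics_mat` of beta values with no missing entries.
#' @param case,control Sample-type labels contrasted (case coded 1).
#' @param n_pcs Number of principal-component covariates (K >= 0).
#' @param analysis_tag Label for the `analysis` column, e.g. `"th_dm"` or
#'   `"tn_dm"`.
#' @return An association tibble of class `assoc_tbl` (`unit_id`, `z`,
#'   `p`, `fdr`, `direction`, `analysis`; `estimate` is the sample-type
#'   coefficient on the beta-value scale).
#' @export
dm_test <- function(mat, case = "tumour", control = "NAT", n_pcs = 5,
                    analysis_tag = paste0(substr(case, 1, 1),
                                          substr(control, 1, 1), "_dm")) {
  keep <- mat$meta$sample_type %in% c(case, control)
  if (!any(mat$meta$sample_type == case) ||
      !any(mat$meta$sample_type == control)) {
    abort("Both contrasted groups must be present.")
  }
  v <- mat$values[, keep, drop = FALSE]
  meta <- mat$meta[keep, , drop = FALSE]
  y_type <- as.numeric(meta$sample_type == case)
  age <- meta$age - mean(meta$age)

  X <- cbind(intercept = 1, sample_type = y_type, age = age, age2 = age^2)
  if (n_pcs > 0) {
    pc <- prcomp(t(v), center = TRUE, scale. = FALSE)
    k <- min(n_pcs, ncol(pc$x))
    X <- cbind(X, pc$x[, seq_len(k), drop = FALSE])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) abort("Design matrix is rank deficient.")
  df <- nrow(X) - ncol(X)
  XtXinv_jj <- chol2inv(qr.R(qrX))[2, 2]

  constant <- apply(v, 1, function(r) var(r) == 0)
  Yt <- t(v)                              # samples x cpgs
  B <- qr.coef(qrX, Yt)                   # p x cpgs
  res <- Yt - X %*% B
  s2 <- colSums(res^2) / df
  est <- B[2, ]
  se <- sqrt(s2 * XtXinv_jj)
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = df)

  out <- tibble(unit_id = rownames(v),
                estimate = unname(ifelse(constant, NA_real_, est)),
                z = unname(ifelse(constant, NA_real_, tval)),
                p = unname(ifelse(constant, NA_real_, pval)))
  n_const <- sum(constant)
  if (n_const > 0) {
    inform(sprintf("%d constant CpG(s) reported as NA.", n_const))
  }
  out$fdr <- NA_real_
  out$fdr[!constant] <- bh_fdr(pmax(out$p[!constant], .Machine$double.xmin))
  out <- out %>%
    mutate(direction = case_when(is.na(.data$z) ~ NA_character_,
                                 .data$z < 0 ~ "hypo",
                                 TRUE ~ "hyper"),
           analysis = analysis_tag) %>%
    arrange(.data$p)
  class(out) <- c("assoc_tbl", class(out))
  out
}
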