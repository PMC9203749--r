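#' Read and validate a GWAS summary-statistics table
#'
#' Loads a delimited file of per-SNP marginal associations (one row per SNP:
#' identifier, position, alleles, effect-allele frequency, effect size,
#' standard error, p-value, sample size), validates every row against the
#' table invariants and drops offending rows with a logged count.
#'
#' Invariants enforced: unique `snp_id`; `se > 0`; `0 < eaf < 1`;
#' `0 < p <= 1`; `n > 0`; single-base alleles.
#'
#' @param path Path to a delimited text file with a header.
#' @param col_map Named character vector mapping the canonical field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `p`, `n`) to the column names used in the file. Defaults
#'   to the canonical names themselves.
#' @param dedupe If `TRUE`, keep the first occurrence of a duplicated
#'   `snp_id` instead of failing.
#' @param delim Field delimiter, default tab.
#'
#' @return A tibble (class `gwas_tbl`) with the canonical columns. The
#'   number of dropped rows is attached as attribute `n_dropped` and
#'   reported via a message.
#' @export
read_gwas <- function(path, col_map = NULL, dedupe = FALSE, delim = "\t") {
  canonical <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "p", "n")
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(col_map)) {
    missing_map <- setdiff(canonical, names(col_map))
    col_map <- c(col_map, setNames(missing_map, missing_map))
    raw <- rename(raw, !!!setNames(unname(col_map[canonical]), canonical))
  }
  absent <- setdiff(canonical, names(raw))
  if (length(absent)) {
    abort(paste0("GWAS file is missing mandatory column(s): ",
                 paste(absent, collapse = ", ")))
  }
  tab <- as_tibble(raw[canonical])
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab$n <- as.numeric(tab$n)

  if (anyDuplicated(tab$snp_id)) {
    if (!dedupe) abort("Duplicate snp_id in GWAS file (set dedupe = TRUE to keep first).")
    tab <- distinct(tab, .data$snp_id, .keep_all = TRUE)
  }
  as_gwas_tbl(tab, source = path)
}

#' Coerce a data frame to a validated GWAS table
#'
#' @param x Data frame with the canonical GWAS columns.
#' @param source Optional provenance label used in messages.
#' @return Tibble of class `gwas_tbl` with invalid rows dropped
#'   (`n_dropped` attribute records how many).
#' @export
as_gwas_tbl <- function(x, source = "gwas") {
  x <- as_tibble(x)
  ok <- !is.na(x$snp_id) & !is.na(x$beta) &
    !is.na(x$se) & x$se > 0 &
    !is.na(x$eaf) & x$eaf > 0 & x$eaf < 1 &
    !is.na(x$p) & x$p > 0 & x$p <= 1 &
    !is.na(x$n) & x$n > 0 &
    x$effect_allele %in% c("A", "C", "G", "T") &
    x$other_allele %in% c("A", "C", "G", "T") &
    x$effect_allele != x$other_allele
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(sprintf("%s: dropped %d invalid row(s), kept %d.",
                   source, n_dropped, sum(ok)))
  }
  out <- x[ok, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("gwas_tbl", class(out))
  out
}

#' Read cis-meQTL / eQTL weight models
#'
#' Loads a long-format table (`unit_id`, `unit_chrom`, `unit_pos`, `snp_id`,
#' `effect_allele`, `other_allele`, `weight`) describing, per CpG or gene,
#' the cis-SNP weights of its genetic prediction model. Entries farther than
#' the cis window from the unit's anchor position are dropped with a
#' warning; units whose weights are all zero are excluded.
#'
#' @param path Path to a delimited text file.
#' @param cis_window Maximum SNP-to-unit distance in bp (default 1 Mb).
#' @param delim Field delimiter.
#' @return A tibble of class `weight_tbl` in the same long format, one row
#'   per retained (unit, SNP) entry.
#' @export
read_weight_models <- function(path, cis_window = 1e6, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- c("unit_id", "unit_chrom", "unit_pos", "snp_id",
            "effect_allele", "other_allele", "weight")
  absent <- setdiff(need, names(raw))
  if (length(absent)) {
    abort(paste0("Weight file is missing column(s): ",
                 paste(absent, collapse = ", ")))
  }
  raw$snp_pos <- if ("snp_pos" %in% names(raw)) as.integer(raw$snp_pos) else NA_integer_
  as_weight_tbl(as_tibble(raw[c(need, "snp_pos")]), cis_window = cis_window)
}

#' Coerce a long data frame of SNP weights to a validated weight table
#'
#' @param x Data frame with columns `unit_id`, `unit_chrom`, `unit_pos`,
#'   `snp_id`, `effect_allele`, `other_allele`, `weight` and optionally
#'   `snp_pos`.
#' @param cis_window Maximum SNP distance from the unit anchor in bp.
#' @return Tibble of class `weight_tbl`.
#' @export
as_weight_tbl <- function(x, cis_window = 1e6) {
  x <- as_tibble(x)
  if (!"snp_pos" %in% names(x)) x$snp_pos <- NA_integer_
  far <- !is.na(x$snp_pos) & abs(x$snp_pos - x$unit_pos) > cis_window
  if (any(far)) {
    warn(sprintf("Dropped %d weight entr%s beyond the %g bp cis window.",
                 sum(far), if (sum(far) == 1) "y" else "ies", cis_window))
    x <- x[!far, , drop = FALSE]
  }
  dup <- duplicated(x[c("unit_id", "snp_id")])
  if (any(dup)) {
    warn(sprintf("Dropped %d duplicated (unit, SNP) weight entr%s.",
                 sum(dup), if (sum(dup) == 1) "y" else "ies"))
    x <- x[!dup, , drop = FALSE]
  }
  zero_units <- x %>%
    group_by(.data$unit_id) %>%
    summarise(all_zero = all(.data$weight == 0), .groups = "drop") %>%
    filter(.data$all_zero) %>%
    pull(.data$unit_id)
  if (length(zero_units)) {
    warn(sprintf("Excluded %d unit(s) with all-zero weights: %s",
                 length(zero_units),
                 paste(head(zero_units, 5), collapse = ", ")))
    x <- x[!x$unit_id %in% zero_units, , drop = FALSE]
  }
  class(x) <- c("weight_tbl", class(x))
  x
}

#' Construct a reference panel object from a dosage matrix
#'
#' A reference panel holds per-sample alt-allele dosages for a set of SNPs
#' and is the source of all LD (covariance / correlation) estimates used by
#' the imputation statistic and the conditional scan. Dosages count the alt
#' allele; monomorphic SNPs are removed.
#'
#' @param dosage Numeric matrix, samples in rows, SNPs in columns, values in
#'   \[0, 2\]. Column names are SNP ids.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, one row per column of `dosage`.
#' @return An object of class `ref_panel`: a list with elements `dosage`,
#'   `snps` (tibble, with derived `freq` = alt-allele frequency and `sd`),
#'   and `n` (sample count).
#' @export
ref_panel <- function(dosage, snps) {
  snps <- as_tibble(snps)
  stopifnot(ncol(dosage) == nrow(snps))
  if (is.null(colnames(dosage))) colnames(dosage) <- snps$snp_id
  stopifnot(identical(colnames(dosage), snps$snp_id))
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) {
    abort("Dosages must lie in [0, 2].")
  }
  sds <- apply(dosage, 2, sd)
  mono <- sds == 0 | is.na(sds)
  if (any(mono)) {
    warn(sprintf("Removed %d monomorphic SNP(s) from panel.", sum(mono)))
    dosage <- dosage[, !mono, drop = FALSE]
    snps <- snps[!mono, , drop = FALSE]
    sds <- sds[!mono]
  }
  snps$freq <- colMeans(dosage) / 2
  snps$sd <- sds
  structure(list(dosage = dosage, snps = snps, n = nrow(dosage)),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d samples x %d SNPs on chrom %s\n",
              x$n, nrow(x$snps), paste(unique(x$snps$chrom), collapse = ",")))
  invisible(x)
}

#' Read a reference panel from disk
#'
#' Two on-disk layouts are supported: a pair of tab-delimited files (a
#' sample-by-SNP dosage matrix whose first column is `sample_id`, plus a SNP
#' map with `snp_id`, `chrom`, `pos`, `ref_allele`, `alt_allele`), or a VCF
#' with diploid GT fields (read via the vcfR package; multi-allelic records
#' are skipped with a warning). Dosages count the alt allele, so GT "0/1"
#' contributes 1.
#'
#' @param path Dosage-matrix TSV or VCF file.
#' @param format `"dosage"` or `"vcf"`.
#' @param snp_map Path to the SNP map TSV (required for `format = "dosage"`).
#' @return A [ref_panel()] object.
#' @export
read_panel <- function(path, format = c("dosage", "vcf"), snp_map = NULL) {
  format <- match.arg(format)
  if (format == "dosage") {
    if (is.null(snp_map)) abort("snp_map is required for dosage format.")
    dos <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    snps <- readr::read_tsv(snp_map, show_col_types = FALSE, progress = FALSE)
    snps$chrom <- as.character(snps$chrom)
    mat <- as.matrix(dos[, -1, drop = FALSE])
    rownames(mat) <- dos[[1]]
    if (ncol(mat) != nrow(snps)) abort("Dosage columns and SNP map rows differ.")
    colnames(mat) <- snps$snp_id
    ref_panel(mat, snps)
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort("Reading VCF panels requires the vcfR package.")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi)) {
      warn(sprintf("Skipped %d multi-allelic VCF record(s).", sum(multi)))
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    count_alt <- function(g) {
      g <- gsub("\\|", "/", g)
      ifelse(is.na(g), NA_real_,
             vapply(strsplit(g, "/"),
                    function(a) sum(a == "1"), numeric(1)))
    }
    mat <- t(apply(gt, 1, count_alt))
    colnames(mat) <- colnames(gt)
    mat <- t(mat)  # samples x snps
    colnames(mat) <- fix$ID
    snps <- tibble(snp_id = fix$ID, chrom = as.character(fix$CHROM),
                   pos = as.integer(fix$POS),
                   ref_allele = fix$REF, alt_allele = fix$ALT)
    ref_panel(mat, snps)
  }
}

#' Write a reference panel to disk
#'
#' @param panel A [ref_panel()] object.
#' @param path Output path for the dosage matrix (TSV) or VCF.
#' @param format `"dosage"` (writes `path` plus a `.snps.tsv` map next to
#'   it) or `"vcf"` (diploid unphased GT records; requires integer dosages).
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(panel, path, format = c("dosage", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage") {
    dos <- as_tibble(panel$dosage)
    dos <- bind_cols_sample_id(dos, rownames(panel$dosage) %||%
                                 paste0("S", seq_len(panel$n)))
    readr::write_tsv(dos, path, progress = FALSE)
    map_path <- paste0(path, ".snps.tsv")
    readr::write_tsv(select(panel$snps, "snp_id", "chrom", "pos",
                            "ref_allele", "alt_allele"),
                     map_path, progress = FALSE)
    invisible(c(path, map_path))
  } else {
    d <- panel$dosage
    if (any(d != round(d))) abort("VCF output requires integer dosages.")
    gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    samples <- rownames(d) %||% paste0("S", seq_len(panel$n))
    header <- c("##fileformat=VCFv4.2",
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
    body <- vapply(seq_len(nrow(panel$snps)), function(i) {
      s <- panel$snps[i, ]
      paste(c(s$chrom, s$pos, s$snp_id, s$ref_allele, s$alt_allele, ".",
              "PASS", ".", "GT", gt_of[as.character(d[, i])]),
            collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
    invisible(path)
  }
}

bind_cols_sample_id <- function(dos, ids) {
  dplyr::bind_cols(tibble(sample_id = ids), dos)
}

#' Harmonize allele frames across GWAS, weight models and reference panel
#'
#' Rotates every source onto the panel's counted (alt) allele: where a
#' GWAS or weight-model effect allele equals the panel's ref allele, the
#' effect sign is flipped (and `eaf` becomes `1 - eaf`); SNPs whose allele
#' pair cannot be reconciled even after swapping, SNPs absent from any one
#' source, and (by default) strand-ambiguous A/T and C/G SNPs are dropped.
#'
#' @param gwas A `gwas_tbl`.
#' @param weights A `weight_tbl`.
#' @param panel A `ref_panel`.
#' @param keep_ambiguous Keep strand-ambiguous (A/T, C/G) SNPs? Default
#'   `FALSE`.
#' @return A list with elements `gwas`, `weights`, `panel` (all restricted
#'   to the shared, reconciled SNP set and oriented to the panel alt allele)
#'   and `report`, a tibble counting SNPs kept / flipped / dropped by
#'   reason.
#' @export
harmonize_alleles <- function(gwas, weights, panel, keep_ambiguous = FALSE) {
  pan <- panel$snps
  shared <- Reduce(intersect, list(gwas$snp_id, unique(weights$snp_id),
                                   pan$snp_id))
  n_absent <- length(unique(c(gwas$snp_id, weights$snp_id, pan$snp_id))) -
    length(shared)

  orient <- function(ea, oa, ref, alt) {
    case_when(
      ea == alt & oa == ref ~ 1,    # already on panel frame
      ea == ref & oa == alt ~ -1,   # swapped: flip sign
      TRUE ~ NA_real_
    )
  }
  is_ambiguous <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
  }

  pan_idx <- match(shared, pan$snp_id)
  g <- gwas[match(shared, gwas$snp_id), ]
  flip_g <- orient(g$effect_allele, g$other_allele,
                   pan$ref_allele[pan_idx], pan$alt_allele[pan_idx])
  amb <- is_ambiguous(g$effect_allele, g$other_allele)
  keep <- !is.na(flip_g) & (keep_ambiguous | !amb)
  n_irrec <- sum(is.na(flip_g))
  n_amb <- sum(!is.na(flip_g) & amb & !keep_ambiguous)

  kept_ids <- shared[keep]
  g <- g[keep, ]
  flip_g <- flip_g[keep]
  flipped <- flip_g < 0
  g$beta <- g$beta * flip_g
  g$eaf <- ifelse(flipped, 1 - g$eaf, g$eaf)
  ea <- g$effect_allele
  g$effect_allele <- ifelse(flipped, g$other_allele, g$effect_allele)
  g$other_allele <- ifelse(flipped, ea, g$other_allele)

  w <- weights[weights$snp_id %in% kept_ids, , drop = FALSE]
  w_idx <- match(w$snp_id, pan$snp_id)
  flip_w <- orient(w$effect_allele, w$other_allele,
                   pan$ref_allele[w_idx], pan$alt_allele[w_idx])
  w <- w[!is.na(flip_w), , drop = FALSE]
  flip_w <- flip_w[!is.na(flip_w)]
  w$weight <- w$weight * flip_w
  wea <- w$effect_allele
  w$effect_allele <- ifelse(flip_w < 0, w$other_allele, w$effect_allele)
  w$other_allele <- ifelse(flip_w < 0, wea, w$other_allele)

  keep_pan <- pan$snp_id %in% kept_ids
  panel2 <- structure(list(dosage = panel$dosage[, keep_pan, drop = FALSE],
                           snps = pan[keep_pan, , drop = FALSE],
                           n = panel$n),
                      class = "ref_panel")

  report <- tibble(
    n_shared = length(shared),
    n_kept = length(kept_ids),
    n_flipped = sum(flipped),
    n_dropped_ambiguous = n_amb,
    n_dropped_irreconcilable = n_irrec,
    n_dropped_absent = n_absent
  )
  list(gwas = g, weights = w, panel = panel2, report = report)
}

#' Write a result table as tab-delimited text
#'
#' Writes any result tibble with a header in a deterministic column order;
#' numeric columns keep full precision so that reloading reproduces the
#' values to better than 1e-12.
#'
#' @param table Data frame to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a GWAS table to tab-delimited text
#'
#' @param gwas A `gwas_tbl`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gwas <- function(gwas, path) {
  write_results(gwas, path)
}
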