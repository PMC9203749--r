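#' Annotate CpGs to genes and genomic categories
#'
#' Interval annotation against gene models with precedence
#' splicing > exonic > 5'/3'-UTR > intronic > upstream / downstream >
#' intergenic. Splicing means within 2 bp of an internal exon boundary
#' (inside the transcript); exonic positions in a coding gene fall in
#' `exonic` when inside the CDS and in `UTR5` / `UTR3` (strand-aware)
#' otherwise; upstream / downstream cover 1 kb beyond the transcript span,
#' strand-aware; non-coding genes yield `ncRNA_exonic` / `ncRNA_intronic`.
#' All overlapping genes are reported (one row per CpG-gene combination);
#' the per-CpG category is the highest-precedence call.
#'
#' @param cpgs Tibble with `cpg_id`, `chrom`, `pos`.
#' @param annotation An `annotation_set` (elements `genes`, `exons`) or a
#'   list with those tibbles.
#' @param genome_length Upper bound on valid positions (errors beyond it).
#' @param flank Upstream / downstream window in bp (default 1000).
#' @param splice_bp Splicing-call distance to exon boundaries (default 2).
#' @return Tibble with `cpg_id`, `category` (per-CpG winning call) and
#'   `genes` (comma-joined ids of all overlapping or flanking genes, NA if
#'   intergenic), plus `hits`, a nested per-gene call in attribute
#'   `"hits"` (tibble `cpg_id`, `gene_id`, `gene_category`).
#' @export
annotate_cpgs <- function(cpgs, annotation, genome_length = NULL,
                          flank = 1000, splice_bp = 2) {
  genes <- annotation$genes
  exons <- annotation$exons
  if (!is.null(genome_length) && any(cpgs$pos > genome_length | cpgs$pos < 1)) {
    abort("CpG position outside the genome.")
  }
  precedence <- c(splicing = 1, exonic = 2, ncRNA_exonic = 2,
                  UTR5 = 3, UTR3 = 3, intronic = 4, ncRNA_intronic = 4,
                  upstream = 5, downstream = 5, intergenic = 6)

  call_one <- function(pos, chrom) {
    g <- genes[genes$chrom == chrom &
                 genes$tx_start - flank <= pos &
                 genes$tx_end + flank >= pos, , drop = FALSE]
    if (!nrow(g)) {
      return(tibble(gene_id = NA_character_, gene_category = "intergenic"))
    }
    purrr::map(seq_len(nrow(g)), function(i) {
      gi <- g[i, ]
      ex <- exons[exons$gene_id == gi$gene_id, , drop = FALSE]
      inside_tx <- pos >= gi$tx_start & pos <= gi$tx_end
      cat <- if (!inside_tx) {
        left <- pos < gi$tx_start
        if ((gi$strand == "+") == left) "upstream" else "downstream"
      } else {
        in_exon <- any(pos >= ex$start & pos <= ex$end)
        internal <- sort(c(ex$start[-1], ex$end[-nrow(ex)]))
        near_junction <- length(internal) > 0 &&
          min(abs(pos - internal)) <= splice_bp
        if (!in_exon && near_junction) {
          "splicing"
        } else if (in_exon) {
          if (!gi$coding) {
            "ncRNA_exonic"
          } else if (pos >= gi$cds_start && pos <= gi$cds_end) {
            "exonic"
          } else {
            before_cds <- pos < gi$cds_start
            if ((gi$strand == "+") == before_cds) "UTR5" else "UTR3"
          }
        } else {
          if (!gi$coding) "ncRNA_intronic" else "intronic"
        }
      }
      tibble(gene_id = gi$gene_id, gene_category = cat)
    }) %>% bind_rows()
  }

  hits <- purrr::map(seq_len(nrow(cpgs)), function(i) {
    mutate(call_one(cpgs$pos[i], cpgs$chrom[i]), cpg_id = cpgs$cpg_id[i])
  }) %>% bind_rows()

  out <- hits %>%
    group_by(.data$cpg_id) %>%
    summarise(
      category = .data$gene_category[which.min(precedence[.data$gene_category])],
      genes = if (all(is.na(.data$gene_id))) NA_character_ else
        paste(sort(unique(.data$gene_id[!is.na(.data$gene_id)])), collapse = ","),
      .groups = "drop") %>%
    left_join(select(cpgs, "cpg_id", "pos"), by = "cpg_id") %>%
    arrange(.data$pos) %>%
    select(-"pos")
  attr(out, "hits") <- hits
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factor: median across genes of the ratio of
#' the sample's count to the gene's geometric mean over all samples
#' (genes with a zero count in any sample are excluded from the median).
#'
#' @param counts Gene-by-sample count matrix.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) abort("No gene is expressed in every sample.")
  apply(counts, 2, function(cnt) {
    exp(median((log(cnt) - log_gm)[use & cnt > 0]))
  })
}

#' Differential expression on counts (normalised OLS stand-in)
#'
#' A documented stand-in for a full negative-binomial analysis: genes with
#' fewer than `min_count` total counts are removed; size factors follow
#' the median-of-ratios rule; each remaining gene's
#' `log2(count / sizefactor + 0.5)` is regressed on the group indicator by
#' ordinary least squares (two-sided t test); fold change is the ratio of
#' normalised group means; BH FDR over tested genes.
#'
#' @param expr An `omics_mat` of counts.
#' @param case,control Contrasted sample types.
#' @param min_count Minimum total count to keep a gene (default 10).
#' @return Tibble of class `de_tbl`: `gene_id`, `fold_change`,
#'   `log2_fc`, `p`, `fdr`, `direction` ("up" iff fold_change > 1).
#' @export
de_test <- function(expr, case = "tumour", control = "NAT", min_count = 10) {
  keep <- expr$meta$sample_type %in% c(case, control)
  counts <- expr$values[, keep, drop = FALSE]
  grp <- expr$meta$sample_type[keep] == case
  if (sum(grp) < 2 || sum(!grp) < 2) abort("Need >= 2 samples per group.")
  tested <- rowSums(counts) >= min_count
  counts <- counts[tested, , drop = FALSE]
  if (!nrow(counts)) abort("No gene passes the count filter.")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  y <- t(log2(norm + 0.5))            # samples x genes
  X <- cbind(1, as.numeric(grp))
  qrX <- qr(X)
  B <- qr.coef(qrX, y)
  res <- y - X %*% B
  df <- nrow(X) - 2
  s2 <- colSums(res^2) / df
  se <- sqrt(s2 * chol2inv(qr.R(qrX))[2, 2])
  tval <- B[2, ] / se
  pval <- 2 * pt(-abs(tval), df = df)
  fc <- rowMeans(norm[, grp, drop = FALSE]) /
    rowMeans(norm[, !grp, drop = FALSE])
  out <- tibble(gene_id = rownames(counts),
                fold_change = unname(fc),
                log2_fc = unname(log2(fc)),
                p = unname(pmax(pval, .Machine$double.xmin))) %>%
    mutate(fdr = bh_fdr(.data$p),
           direction = ifelse(.data$fold_change > 1, "up", "down")) %>%
    arrange(.data$p)
  class(out) <- c("de_tbl", class(out))
  out
}

#' Distance-window scan for CpG-associated differentially expressed genes
#'
#' For each window half-width w, collects the genes overlapping (even
#' partially) the +/- w interval around any CpG in the set, computes the
#' proportion that are differentially expressed, and tests it against the
#' genome-wide DE rate by a one-sided (greater) exact binomial. The
#' selected window maximises the drop in DEG proportion to the next larger
#' window (ties broken toward the smaller window); the selected DEG set is
#' the DEGs within that window.
#'
#' @param cpgs Tibble with `cpg_id`, `chrom`, `pos` for the CpG set.
#' @param de A `de_tbl` from [de_test()].
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `tx_start`,
#'   `tx_end`).
#' @param windows Increasing vector of half-widths in bp.
#' @param null_rate Genome-wide DE rate in (0, 1); default computed from
#'   `de` as the fraction with `fdr < de_fdr`.
#' @param de_fdr FDR threshold defining a DEG.
#' @return Object of class `window_scan`: list with `scan` (tibble per
#'   window: n_genes, n_de, proportion, p_value), `selected_window`,
#'   `selected_genes` (DEG ids within it).
#' @export
distance_window_scan <- function(cpgs, de, genes,
                                 windows = c(1e3, 5e3, 1e4, 2.5e4, 5e4,
                                             1e5, 5e5, 1e6, 5e6, 1e7),
                                 null_rate = NULL, de_fdr = 0.05) {
  if (length(windows) < 2) abort("Need at least 2 windows.")
  if (is.unsorted(windows, strictly = TRUE)) abort("Windows must be strictly increasing.")
  deg <- de$gene_id[de$fdr < de_fdr]
  if (is.null(null_rate)) null_rate <- length(deg) / nrow(de)
  if (null_rate <= 0 || null_rate >= 1) abort("null_rate must lie in (0, 1).")

  genes <- genes[genes$gene_id %in% de$gene_id, , drop = FALSE]
  per_window <- purrr::map(windows, function(w) {
    hit <- purrr::map_lgl(seq_len(nrow(genes)), function(i) {
      any(cpgs$chrom == genes$chrom[i] &
            genes$tx_start[i] <= cpgs$pos + w &
            genes$tx_end[i] >= cpgs$pos - w)
    })
    ids <- genes$gene_id[hit]
    n <- length(ids)
    k <- sum(ids %in% deg)
    tibble(window = w, n_genes = n, n_de = k,
           proportion = ifelse(n > 0, k / n, NA_real_),
           p_value = ifelse(n > 0,
                            binom.test(k, n, null_rate,
                                       alternative = "greater")$p.value,
                            NA_real_),
           genes = list(ids))
  }) %>% bind_rows()

  props <- per_window$proportion
  drops <- props[-length(props)] - props[-1]
  drops[is.na(drops)] <- -Inf
  sel <- which.max(drops)              # ties -> smaller window
  sel_window <- windows[sel]
  sel_genes <- intersect(per_window$genes[[sel]], deg)
  structure(list(scan = select(per_window, -"genes"),
                 selected_window = sel_window,
                 selected_genes = sel_genes,
                 null_rate = null_rate),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("<window_scan> selected window %g bp, %d DEG(s), null rate %.3f\n",
              x$selected_window, length(x$selected_genes), x$null_rate))
  print(x$scan)
  invisible(x)
}

#' eQTL / meQTL SNP-overlap enrichment per gene
#'
#' Associates genes to a CpG set when the SNPs of the gene's expression
#' model are enriched for the CpG set's meQTL SNPs: per gene, `k` = eQTL
#' SNPs shared with the union of the CpGs' meQTL SNPs, `n` = eQTL SNPs;
#' the null proportion is the median of `k / n` over genes with at least
#' one overlapping SNP (or a supplied override); one-sided (greater)
#' binomial with BH FDR.
#'
#' @param meqtl_weights `weight_tbl` of the CpG set's methylation models.
#' @param eqtl_weights `weight_tbl` of expression models (units = genes).
#' @param null_rate Optional null proportion override in (0, 1).
#' @param fdr FDR threshold flagging linked genes.
#' @return Tibble: `gene_id`, `k`, `n`, `observed`, `p0`, `p_value`,
#'   `fdr`, `linked`.
#' @export
eqtl_overlap_enrichment <- function(meqtl_weights, eqtl_weights,
                                    null_rate = NULL, fdr = 0.05) {
  meqtl_snps <- unique(meqtl_weights$snp_id)
  per_gene <- eqtl_weights %>%
    group_by(gene_id = .data$unit_id) %>%
    summarise(n = dplyr::n_distinct(.data$snp_id),
              k = dplyr::n_distinct(.data$snp_id[.data$snp_id %in% meqtl_snps]),
              .groups = "drop") %>%
    mutate(observed = .data$k / .data$n)
  with_overlap <- per_gene$observed[per_gene$k >= 1]
  if (is.null(null_rate)) {
    if (!length(with_overlap)) abort("No gene has an overlapping SNP; null proportion undefined.")
    null_rate <- median(with_overlap)
  }
  if (null_rate <= 0 || null_rate >= 1) abort("null_rate must lie in (0, 1).")
  thr <- fdr
  per_gene %>%
    mutate(p0 = null_rate,
           p_value = purrr::map2_dbl(.data$k, .data$n, function(k, n) {
             binom.test(k, n, null_rate, alternative = "greater")$p.value
           }),
           fdr = bh_fdr(.data$p_value),
           linked = .data$fdr < thr) %>%
    arrange(.data$p_value)
}

#' Mediation (conditional differential expression) regression
#'
#' Per CpG-gene pair, fits
#' `log2 expression ~ sample_type + methylation + sample_type : methylation`
#' on matched samples; the interaction coefficient's p-value measures the
#' conditional association of expression with sample type given the CpG's
#' methylation. BH FDR across tested pairs. Pairs whose design is
#' collinear (e.g. methylation constant) give NA rows excluded from the
#' FDR denominator.
#'
#' @param expr An `omics_mat` of counts (normalised internally to
#'   `log2(count / sizefactor + 1)`).
#' @param meth An `omics_mat` of beta values.
#' @param pairs Tibble with `gene_id` and `cpg_id` columns.
#' @param case,control Contrasted sample types.
#' @return Tibble of class `mediation_tbl`: `gene_id`, `cpg_id`,
#'   `interaction`, `p`, `fdr`.
#' @export
mediation_test <- function(expr, meth, pairs, case = "tumour",
                           control = "NAT") {
  shared <- intersect(expr$meta$sample_id, meth$meta$sample_id)
  meta <- expr$meta[match(shared, expr$meta$sample_id), ]
  keep <- meta$sample_type %in% c(case, control)
  shared <- shared[keep]
  if (!length(shared)) abort("No matched samples in the contrasted groups.")
  st <- as.numeric(expr$meta$sample_type[match(shared, expr$meta$sample_id)] == case)
  if (all(st == 1) || all(st == 0)) abort("Both groups must be present.")
  counts <- expr$values[, shared, drop = FALSE]
  sf <- size_factors(counts)
  logex <- log2(sweep(counts, 2, sf, "/") + 1)
  bv <- meth$values[, shared, drop = FALSE]

  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene_id[i]; cp <- pairs$cpg_id[i]
    if (!g %in% rownames(logex) || !cp %in% rownames(bv)) return(NULL)
    m <- bv[cp, ]
    y <- logex[g, ]
    ok <- !is.na(m) & !is.na(y)
    X <- cbind(1, st[ok], m[ok], st[ok] * m[ok])
    if (qr(X)$rank < 4L) {
      inform(sprintf("Pair %s / %s: collinear design, NA reported.", g, cp))
      return(tibble(gene_id = g, cpg_id = cp,
                    interaction = NA_real_, p = NA_real_))
    }
    fit <- lm(y[ok] ~ st[ok] + m[ok] + st[ok]:m[ok])
    sm <- summary(fit)$coefficients
    tibble(gene_id = g, cpg_id = cp,
           interaction = sm[4, 1], p = sm[4, 4])
  })
  out <- bind_rows(purrr::compact(rows))
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- bh_fdr(pmax(out$p[ok], .Machine$double.xmin))
  class(out) <- c("mediation_tbl", class(out))
  out
}

#' Direction concordance of CpG methylation and gene expression
#'
#' Classifies CpG-gene pairs by the relation between the CpG's
#' differential-methylation direction and the gene's differential-
#' expression direction: negative correlation = (hypo, up) or
#' (hyper, down); positive = (hypo, down) or (hyper, up). Pairs missing
#' either result are excluded and counted.
#'
#' @param dm An `assoc_tbl` carrying per-CpG `direction`.
#' @param de A `de_tbl` carrying per-gene `direction`.
#' @param pairs Tibble with `cpg_id` and `gene_id`.
#' @return List: `counts` (tibble with `negative`, `positive`,
#'   `n_excluded`) and `pairs` (per-pair tibble with `correlation`).
#' @export
direction_concordance <- function(dm, de, pairs) {
  tab <- pairs %>%
    left_join(select(dm, cpg_id = "unit_id", dm_direction = "direction"),
              by = "cpg_id") %>%
    left_join(select(de, "gene_id", de_direction = "direction"),
              by = "gene_id")
  complete <- !is.na(tab$dm_direction) & !is.na(tab$de_direction)
  tab <- mutate(tab[complete, , drop = FALSE],
                correlation = ifelse(
                  (.data$dm_direction == "hypo") == (.data$de_direction == "up"),
                  "negative", "positive"))
  list(counts = tibble(negative = sum(tab$correlation == "negative"),
                       positive = sum(tab$correlation == "positive"),
                       n_excluded = sum(!complete)),
       pairs = tab)
}

#' Gene-set enrichment by Fisher's exact test
#'
#' Per pathway, a 2x2 Fisher exact test of the gene set against the
#' declared background universe with Bonferroni adjustment; pathways with
#' fewer than `min_overlap` genes in the set are excluded.
#'
#' @param gene_set Character vector of genes.
#' @param pathways Named list of character vectors (pathway -> genes).
#' @param universe Background gene universe.
#' @param min_overlap Minimum genes shared between set and pathway
#'   (default 2).
#' @return Tibble: `pathway`, `n_overlap`, `n_pathway`, `p`,
#'   `p_adjusted` (Bonferroni over tested pathways).
#' @export
gene_set_fisher <- function(gene_set, pathways, universe, min_overlap = 2) {
  if (!length(pathways)) abort("Empty pathway database.")
  gene_set <- intersect(gene_set, universe)
  rows <- purrr::imap(pathways, function(genes, name) {
    genes <- intersect(genes, universe)
    k <- length(intersect(gene_set, genes))
    if (k < min_overlap) return(NULL)
    tab <- matrix(c(k,
                    length(gene_set) - k,
                    length(genes) - k,
                    length(universe) - length(gene_set) - length(genes) + k),
                  2, 2)
    tibble(pathway = name, n_overlap = k, n_pathway = length(genes),
           p = fisher.test(tab, alternative = "greater")$p.value)
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out)) {
    out$p_adjusted <- pmin(out$p * nrow(out), 1)
    out <- arrange(out, .data$p)
  }
  out
}
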