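simple_annotation <- function() {
  genes <- tibble::tibble(
    gene_id = c("gplus", "gminus", "gnc"),
    chrom = "1", strand = c("+", "-", "+"),
    tx_start = c(10000L, 30000L, 50000L),
    tx_end = c(17999L, 37999L, 57999L),
    cds_start = c(10200L, 30200L, NA),
    cds_end = c(17799L, 37799L, NA),
    coding = c(TRUE, TRUE, FALSE))
  exons <- tidyr::crossing(gene_id = genes$gene_id, exon = 1:3) %>%
    dplyr::left_join(dplyr::select(genes, gene_id, tx_start), by = "gene_id") %>%
    dplyr::mutate(start = tx_start + c(0L, 3000L, 7000L)[exon],
                  end = tx_start + c(999L, 3999L, 7999L)[exon]) %>%
    dplyr::select(gene_id, exon, start, end)
  list(genes = genes, exons = exons)
}

test_that("the interval annotator applies category precedence", {
  ann <- simple_annotation()
  cpgs <- tibble::tibble(
    cpg_id = c("in_cds", "in_utr5", "in_utr3", "intron", "splice",
               "up_plus", "down_plus", "up_minus", "between",
               "nc_exon", "nc_intron"),
    chrom = "1",
    pos = c(10500L,          # CDS of + gene
            10100L,          # before CDS on + strand
            17900L,          # after CDS on + strand
            12000L,          # intron
            11001L,          # 1 bp into the intron
            9500L,           # 500 bp 5' of + TSS
            18500L,          # 500 bp 3' of + gene
            38500L,          # 500 bp beyond - gene's tx_end = upstream
            25000L,          # between genes
            50500L, 52000L)) # non-coding gene
  res <- annotate_cpgs(cpgs, ann)
  got <- setNames(res$category, res$cpg_id)
  expect_equal(got[["in_cds"]], "exonic")
  expect_equal(got[["in_utr5"]], "UTR5")
  expect_equal(got[["in_utr3"]], "UTR3")
  expect_equal(got[["intron"]], "intronic")
  expect_equal(got[["splice"]], "splicing")
  expect_equal(got[["up_plus"]], "upstream")
  expect_equal(got[["down_plus"]], "downstream")
  expect_equal(got[["up_minus"]], "upstream")
  expect_equal(got[["between"]], "intergenic")
  expect_equal(got[["nc_exon"]], "ncRNA_exonic")
  expect_equal(got[["nc_intron"]], "ncRNA_intronic")
  expect_error(annotate_cpgs(tibble::tibble(cpg_id = "x", chrom = "1",
                                            pos = 99999999L),
                             ann, genome_length = 2e6), "outside")
})

test_that("differential expression stand-in normalises and filters correctly", {
  set.seed(3)
  n <- 20
  base <- matrix(rnbinom(5 * n, mu = 100, size = 10), 5, n)
  rownames(base) <- paste0("g", 1:5)
  colnames(base) <- sprintf("s%02d", 1:n)
  grp <- rep(c("tumour", "NAT"), each = n / 2)
  base["g2", grp == "tumour"] <- base["g2", grp == "tumour"] * 2  # doubled
  base["g5", ] <- c(rep(0L, n - 1), 9L)                           # < 10 counts
  expr <- omics_mat(base, tibble::tibble(sample_id = colnames(base),
                                         sample_type = grp, age = 50))
  de <- de_test(expr)
  expect_false("g5" %in% de$gene_id)
  expect_equal(de$fold_change[de$gene_id == "g2"], 2, tolerance = 0.15)
  expect_equal(de$direction[de$gene_id == "g2"], "up")

  # fold changes invariant to global library rescaling
  scaled <- base[1:4, ]
  scaled[, 1:5] <- scaled[, 1:5] * 4
  expr2 <- omics_mat(scaled, expr$meta)
  de2 <- de_test(expr2)
  expect_equal(de2$fold_change, de$fold_change[match(de2$gene_id, de$gene_id)],
               tolerance = 1e-9)
})

test_that("the stand-in DE agrees with DESeq2 on strong signals", {
  skip_if_not_installed("DESeq2")
  st <- default_study()
  de <- de_test(st$expr)
  cts <- st$expr$values[rowSums(st$expr$values) >= 10, ]
  col <- data.frame(condition = factor(st$expr$meta$sample_type,
                                       levels = c("NAT", "tumour")))
  dds <- DESeq2::DESeqDataSetFromMatrix(cts, col, ~condition)
  res <- suppressMessages(DESeq2::results(DESeq2::DESeq(dds, quiet = TRUE)))
  shared <- intersect(rownames(res), de$gene_id)
  lfc_ours <- de$log2_fc[match(shared, de$gene_id)]
  lfc_ds <- res[shared, "log2FoldChange"]
  expect_gt(cor(lfc_ours, lfc_ds), 0.95)
  truth <- st$truth$genes
  sig_true <- truth$gene_id[truth$is_de]
  expect_setequal(intersect(shared[res[shared, "padj"] < 0.05 &
                                     abs(lfc_ds) > 0.5], sig_true),
                  intersect(de$gene_id[de$fdr < 0.05 & abs(de$log2_fc) > 0.5],
                            sig_true))
})

test_that("window scan picks the maximum enrichment drop with small-window ties", {
  # synthetic proportions: construct geneset layouts reproducing the rule
  cpgs <- tibble::tibble(cpg_id = "cg1", chrom = "1", pos = 100000L)
  # ten genes at each of four clean distances from the CpG
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40), chrom = "1",
    tx_start = 100000L + rep(c(500L,     # within 1 kb
                               9000L,    # within 10 kb only
                               20000L,   # within 25 kb only
                               40000L),  # within 50 kb only
                             each = 10))
  genes$tx_end <- genes$tx_start + 99L
  # DE truth: proportions 0.70 -> 0.65 -> 0.64 -> 0.53 like the worked rule
  de_flags <- c(rep(TRUE, 7), rep(FALSE, 3),
                rep(TRUE, 6), rep(FALSE, 4),
                rep(TRUE, 3), rep(FALSE, 7),
                rep(TRUE, 0), rep(FALSE, 10))
  de <- tibble::tibble(gene_id = genes$gene_id,
                       fold_change = 2, log2_fc = 1,
                       p = ifelse(de_flags, 1e-6, 0.9),
                       fdr = ifelse(de_flags, 1e-4, 0.95),
                       direction = "up")
  scan <- distance_window_scan(cpgs, de, genes,
                               windows = c(1e3, 1e4, 2.5e4, 5e4),
                               null_rate = 0.4)
  props <- scan$scan$proportion
  expect_equal(props, c(0.7, 0.65, 16 / 30, 0.4), tolerance = 1e-9)
  expect_equal(scan$selected_window, 2.5e4)   # the 25k -> 50k drop is maximal

  # flat proportions select the smallest window
  de_all <- dplyr::mutate(de, p = 1e-6, fdr = 1e-4)
  scan2 <- distance_window_scan(cpgs, de_all, genes,
                                windows = c(1e3, 1e4, 2.5e4, 5e4),
                                null_rate = 0.4)
  expect_equal(scan2$selected_window, 1e3)

  # DEG sets are nested across increasing windows
  sets <- purrr::map(scan$scan$window, function(w) {
    s <- distance_window_scan(cpgs, de, genes,
                              windows = c(w, 2e7), null_rate = 0.4)
    s$scan$n_genes[1]
  })
  expect_true(all(diff(unlist(sets)) >= 0))
  expect_error(distance_window_scan(cpgs, de, genes, windows = 1e3,
                                    null_rate = 0.4), "2 windows")
})

test_that("the published window-scan drop picks 10 kb", {
  # proportions as printed: 1 kb 56.52%, 10 kb 54.35%, 25 kb 43.75%, 50 kb 39.13%
  props <- c(0.5652, 0.5435, 0.4375, 0.3913)
  drops <- props[-length(props)] - props[-1]
  expect_equal(which.max(drops), 2)   # the 10 kb -> 25 kb drop is maximal
})

test_that("eQTL overlap enrichment uses the median null and flags exact matches", {
  meqtl <- tibble::tibble(unit_id = "cg1", snp_id = paste0("rs", 1:5),
                          weight = 1)
  eqtl <- tibble::tibble(
    unit_id = rep(c("gA", "gB", "gC"), each = 5),
    snp_id = c(paste0("rs", 1:5),          # gA: all 5 overlap
               paste0("rs", c(1, 11:14)),  # gB: 1 of 5
               paste0("rs", 21:25)),       # gC: none
    weight = 1)
  res <- eqtl_overlap_enrichment(meqtl, eqtl, fdr = 0.05)
  expect_equal(res$p0[1], median(c(1, 0.2)))  # genes with >= 1 overlap
  gC <- res[res$gene_id == "gC", ]
  expect_equal(gC$k, 0)
  expect_equal(gC$p_value, 1)
  gA <- eqtl_overlap_enrichment(meqtl, eqtl, null_rate = 0.0092)
  expect_lt(gA$p_value[gA$gene_id == "gA"], 1e-10)
  # all genes with identical overlap proportion: p0 equals it, p >= 0.5
  eq <- tibble::tibble(unit_id = rep(c("g1", "g2"), each = 5),
                       snp_id = c(paste0("rs", c(1, 31:34)),
                                  paste0("rs", c(2, 41:44))), weight = 1)
  res_eq <- eqtl_overlap_enrichment(meqtl, eq)
  expect_equal(unique(res_eq$p0), 0.2)
  expect_true(all(res_eq$p_value >= 0.5))
})

test_that("mediation regression recovers planted interactions and flags collinearity", {
  st <- default_study()
  truth <- st$truth$genes
  pairs <- dplyr::filter(truth, !is.na(linked_cpg)) %>%
    dplyr::select(gene_id, cpg_id = linked_cpg)
  clean <- pc1_outlier_removal(qc_and_impute(st$meth))$mat
  med <- mediation_test(st$expr, clean, pairs)
  expect_lt(median(med$p, na.rm = TRUE), 0.01)

  # pure main effects leave the interaction null
  cfg0 <- sim_config(seed = 61, mediation_effect = 0)
  st0 <- simulate_study(cfg0)
  pairs0 <- dplyr::filter(st0$truth$genes, !is.na(linked_cpg)) %>%
    dplyr::select(gene_id, cpg_id = linked_cpg)
  med0 <- mediation_test(st0$expr, st0$meth, pairs0)
  expect_gt(min(med0$p, na.rm = TRUE), 0.01 / nrow(med0))

  # constant methylation -> collinear design -> NA
  m2 <- st$meth
  m2$values[pairs$cpg_id[1], ] <- 0.5
  expect_message(
    med2 <- mediation_test(st$expr, m2, pairs[1, , drop = FALSE]),
    "collinear")
  expect_true(is.na(med2$p[1]))
})

test_that("mediation p-values are invariant to affine methylation rescaling", {
  st <- default_study()
  pairs <- dplyr::filter(st$truth$genes, !is.na(linked_cpg)) %>%
    dplyr::select(gene_id, cpg_id = linked_cpg) %>% head(3)
  m1 <- mediation_test(st$expr, st$meth, pairs)
  m2mat <- st$meth
  m2mat$values <- 0.25 * m2mat$values + 0.1
  m2 <- mediation_test(st$expr, m2mat, pairs)
  expect_equal(m2$p, m1$p, tolerance = 1e-8)
  expect_equal(m2$interaction, m1$interaction / 0.25, tolerance = 1e-6)
})

test_that("direction concordance partitions complete pairs", {
  dm <- tibble::tibble(unit_id = c("c1", "c2", "c3"),
                       direction = c("hypo", "hyper", "hypo"))
  de <- tibble::tibble(gene_id = c("g1", "g2"),
                       direction = c("up", "up"))
  pairs <- tibble::tibble(cpg_id = c("c1", "c2", "c3", "c4"),
                          gene_id = c("g1", "g2", "gX", "g1"))
  res <- direction_concordance(dm, de, pairs)
  expect_equal(res$counts$negative, 1)   # (hypo, up)
  expect_equal(res$counts$positive, 1)   # (hyper, up)
  expect_equal(res$counts$n_excluded, 2)
  expect_equal(res$counts$negative + res$counts$positive, nrow(res$pairs))
})

test_that("gene-set Fisher enrichment honours the two-gene rule", {
  universe <- paste0("g", 1:50)
  gs <- paste0("g", 1:10)
  pathways <- list(self = gs,
                   one_overlap = c("g1", paste0("g", 40:45)),
                   disjoint = paste0("g", 30:39))
  res <- gene_set_fisher(gs, pathways, universe)
  expect_false("one_overlap" %in% res$pathway)
  expect_false("disjoint" %in% res$pathway)   # zero overlap < 2
  # hypergeometric oracle for the self pathway
  oracle <- stats::phyper(10 - 1, 10, 40, 10, lower.tail = FALSE)
  expect_equal(res$p[res$pathway == "self"], oracle, tolerance = 1e-12)
  expect_error(gene_set_fisher(gs, list(), universe), "Empty")
})
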