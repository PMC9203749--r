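frr_row <- function(eaf, beta, se) {
  tibble::tibble(eaf = eaf, beta = beta, se = se)
}

test_that("familial-risk contribution follows the printed formula", {
  # single SNP p = 0.5, beta = 0.1, tau = 0, lambda = 2
  expect_equal(frr_contribution(frr_row(0.5, 0.1, 0), lambda = 2),
               0.25 * 0.01 / log(2), tolerance = 1e-12)
  # beta^2 = tau^2 contributes nothing
  expect_equal(frr_contribution(frr_row(0.3, 0.1, 0.1), lambda = 2), 0)
  # additivity over SNPs
  a <- frr_row(0.2, 0.15, 0.02); b <- frr_row(0.4, -0.1, 0.03)
  expect_equal(frr_contribution(dplyr::bind_rows(a, b), 2.5),
               frr_contribution(a, 2.5) + frr_contribution(b, 2.5))
  # invariance to effect-allele flips
  flipped <- dplyr::mutate(a, eaf = 1 - eaf, beta = -beta)
  expect_equal(frr_contribution(flipped, 2), frr_contribution(a, 2))
  # conventional factor-2 variant doubles the result
  expect_equal(frr_contribution(a, 2, factor2 = TRUE),
               2 * frr_contribution(a, 2))
  expect_error(frr_contribution(a, 1), "lambda")
})

test_that("ld_r2 is a symmetric squared correlation", {
  st <- default_study()
  p <- st$panel
  ids <- p$snps$snp_id
  expect_equal(ld_r2(p, ids[1], ids[1]), 1)
  expect_equal(ld_r2(p, ids[1], ids[7]), ld_r2(p, ids[7], ids[1]))
  # distant SNPs under weak LD are near-independent
  far <- ld_r2(p, ids[1], ids[length(ids)])
  expect_lt(far, 0.05)
  expect_error(ld_r2(p, ids[1], "nope"), "nope")
})

test_that("region classification applies the printed boundaries", {
  gwas <- as_gwas_tbl(tibble::tibble(
    snp_id = c("s1", "s2", "s3"), chrom = "1",
    pos = c(1000L, 2000L, 3000L),
    effect_allele = "A", other_allele = "C",
    eaf = 0.3, beta = 0.1, se = 0.02,
    p = c(4e-8, 5e-7, 1e-4), n = 1000))
  cls <- function(p) {
    g <- gwas; g$p <- c(p, 0.5, 0.5)
    classify_region(tibble::tibble(cpg_id = "cg", chrom = "1", pos = 1500L),
                    g)$region_class
  }
  expect_equal(cls(4e-8), "genome_wide_significant")
  expect_equal(cls(5e-8), "genome_wide_significant")   # boundary inclusive
  expect_equal(cls(5e-7), "suggestive")
  expect_equal(cls(1e-5), "suggestive")
  expect_equal(cls(1e-4), "novel")
  expect_warning(
    res <- classify_region(tibble::tibble(cpg_id = "cg", chrom = "2",
                                          pos = 1500L), gwas),
    "novel")
  expect_equal(res$region_class, "novel")
})

test_that("orthogonal causal SNPs are both selected with near-marginal p", {
  cfg <- sim_config(seed = 41, m_snps = 20, ld_decay = 0, n_cohort = 2000)
  panel <- simulate_panel(cfg)
  gen <- attr(panel, "generator")
  set.seed(42)
  G <- methlink:::sim_genotypes(2000, gen$freq, gen$theta)
  colnames(G) <- gen$snp_id
  y <- 0.25 * G[, 3] - 0.25 * G[, 12] + rnorm(2000)
  gwas <- methlink:::marginal_gwas(G, y, panel)
  scan <- conditional_scan(panel$snps$snp_id, gwas, panel)
  expect_true(all(c(gen$snp_id[3], gen$snp_id[12]) %in% scan$selected$snp_id))
  top2 <- scan$selected[scan$selected$snp_id %in% gen$snp_id[c(3, 12)], ]
  # conditioning on orthogonal SNPs barely moves the p-value
  expect_lt(max(abs(log10(top2$p_cond_entry) - log10(top2$p_gwas))), 0.5)
})

test_that("duplicate SNPs are excluded by the collinearity cap", {
  cfg <- sim_config(seed = 43, m_snps = 10, ld_decay = 0)
  panel <- simulate_panel(cfg)
  dup <- panel
  dup$dosage <- cbind(panel$dosage, dupSNP = panel$dosage[, 1])
  dup$snps <- dplyr::bind_rows(panel$snps,
                               dplyr::mutate(panel$snps[1, ],
                                             snp_id = "dupSNP",
                                             pos = pos + 1L))
  set.seed(44)
  gen <- attr(panel, "generator")
  G <- methlink:::sim_genotypes(1000, gen$freq, gen$theta)
  colnames(G) <- gen$snp_id
  G <- cbind(G, dupSNP = G[, 1])
  y <- 0.3 * G[, 1] + rnorm(1000)
  gwas <- methlink:::marginal_gwas(G, y, dup)
  scan <- conditional_scan(dup$snps$snp_id, gwas, dup)
  expect_false(all(c(gwas$snp_id[1], "dupSNP") %in% scan$selected$snp_id))
  # and every selected pair respects the cap
  if (nrow(scan$selected) > 1) {
    combs <- utils::combn(scan$selected$snp_id, 2)
    r2s <- apply(combs, 2, function(s) ld_r2(dup, s[1], s[2]))
    expect_true(all(r2s <= 0.9))
  }
})

test_that("summary-level joint fit matches individual-level regression in the exact-LD limit", {
  cfg <- sim_config(seed = 45, m_snps = 20, ld_decay = 0.6, n_cohort = 2000)
  panel <- simulate_panel(cfg)
  gen <- attr(panel, "generator")
  set.seed(46)
  G <- methlink:::sim_genotypes(2000, gen$freq, gen$theta)
  colnames(G) <- gen$snp_id
  y <- 0.12 * G[, 5] - 0.12 * G[, 15] + rnorm(2000)
  y <- y / sd(y)
  cohort_panel <- ref_panel(G, panel$snps)
  gwas <- methlink:::marginal_gwas(G, y, cohort_panel)
  ids <- gen$snp_id[c(5, 15, 10)]
  ld <- ld_matrix(cohort_panel, ids)
  fit <- methlink:::joint_from_summary(ids, gwas, ld$corr,
                                       setNames(cohort_panel$snps$freq,
                                                cohort_panel$snps$snp_id),
                                       n = 2000)
  ref <- coef(lm(y ~ G[, ids]))[-1]
  expect_equal(unname(fit$beta_joint), unname(ref), tolerance = 0.05)
})

test_that("the conditional scan matches stepwise regression on individual data", {
  agree <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = 300 + s, m_snps = 20, ld_decay = 0.6,
                      n_cohort = 2000)
    panel <- simulate_panel(cfg)
    gen <- attr(panel, "generator")
    set.seed(400 + s)
    G <- methlink:::sim_genotypes(2000, gen$freq, gen$theta)
    colnames(G) <- gen$snp_id
    causal <- c(4, 16)
    y <- 0.15 * G[, causal[1]] - 0.15 * G[, causal[2]] + rnorm(2000)
    gwas <- methlink:::marginal_gwas(G, y, panel)
    scan <- conditional_scan(panel$snps$snp_id, gwas, panel)
    oracle <- stepwise_lm_oracle(G, y)
    setequal(scan$selected$snp_id, oracle)
  }, logical(1))
  expect_gte(sum(agree), 4)
})

test_that("region pooling merges CpGs within the window", {
  cpgs <- tibble::tibble(cpg_id = c("a", "b", "c"), chrom = "1",
                         pos = c(1e6, 1.5e6, 4e6))
  pooled <- pool_regions(cpgs)
  expect_equal(dplyr::n_distinct(pooled$region_id), 2)
  expect_equal(pooled$region_id[1], pooled$region_id[2])
})

test_that("fixed-effect meta-analysis matches closed forms", {
  g <- function(beta, se) as_gwas_tbl(tibble::tibble(
    snp_id = "rs1", chrom = "1", pos = 100L,
    effect_allele = "A", other_allele = "C", eaf = 0.3,
    beta = beta, se = se, p = 0.5, n = 1000))
  # identical studies: beta unchanged, se / sqrt(2), Q = 0, p_het = 1
  m <- meta_fixed(list(g(0.2, 0.05), g(0.2, 0.05)))
  expect_equal(m$beta, 0.2)
  expect_equal(m$se, 0.05 / sqrt(2))
  expect_equal(m$q, 0)
  expect_equal(m$p_het, 1)
  # opposite effects: beta = 0, Q = 2 beta^2 / s^2
  m2 <- meta_fixed(list(g(0.2, 0.05), g(-0.2, 0.05)))
  expect_equal(m2$beta, 0)
  expect_equal(m2$q, 2 * 0.2^2 / 0.05^2)
  expect_true(m2$heterogeneous)
  # k identical studies: se = s / sqrt(k)
  m4 <- meta_fixed(rep(list(g(0.1, 0.04)), 4))
  expect_equal(m4$se, 0.04 / sqrt(4))
  # single study: output equals input, p_het NA
  m1 <- meta_fixed(list(g(0.3, 0.06)))
  expect_equal(m1$beta, 0.3)
  expect_equal(m1$se, 0.06)
  expect_true(is.na(m1$p_het))
  # combined se never exceeds the smallest per-study se
  expect_lte(m2$se, 0.05)
  # irreconcilable allele frames are dropped with a warning
  flip <- g(0.2, 0.05)
  flip$effect_allele <- "G"
  expect_warning(m0 <- meta_fixed(list(g(0.2, 0.05), flip)), "allele")
  expect_equal(nrow(m0), 0)
})

test_that("pleiotropy linking uses shared SNPs or moderate LD", {
  st <- default_study()
  p <- st$panel
  ids <- p$snps$snp_id
  # shared SNP links regardless of LD
  res <- pleiotropy_link(ids[1:2], c(ids[2], ids[50]), p)
  expect_true(res$linked)
  expect_equal(res$shared, ids[2])
  # duplicate column gives r2 = 1 > 0.4 -> linked via LD
  dup <- p
  dup$dosage <- cbind(p$dosage, twin = p$dosage[, 1])
  dup$snps <- dplyr::bind_rows(p$snps,
                               dplyr::mutate(p$snps[1, ], snp_id = "twin",
                                             pos = pos + 1L))
  res2 <- pleiotropy_link(ids[1], "twin", dup)
  expect_true(res2$linked)
  expect_gt(res2$pairs$r2[1], 0.4)
  # distant independent SNPs are not linked
  res3 <- pleiotropy_link(ids[1], ids[length(ids)], p)
  expect_false(res3$linked)
  expect_false(pleiotropy_link(character(0), ids[1], p)$linked)
})

test_that("LD-block assignment partitions assigned CpGs", {
  blocks <- tibble::tibble(block_id = c("b1", "b2"), chrom = "1",
                           start = c(1L, 1001L), end = c(1000L, 2000L))
  cpgs <- tibble::tibble(cpg_id = c("c1", "c2", "c3", "c4"), chrom = "1",
                         pos = c(500L, 1500L, 1600L, 5000L))
  res <- ld_block_assign(cpgs, blocks)
  expect_equal(res$assignment$block_id, c("b1", "b2", "b2", "unassigned"))
  expect_equal(sum(res$occupancy$n_cpgs), 3)
})
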