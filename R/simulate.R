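#' Simulation configuration
#'
#' Bundles every parameter of the synthetic data generator. The defaults
#' are the package's reference study conditions: a 2 Mb single-chromosome
#' genome carrying 200 SNPs, 40 CpGs (8 causal) and 30 genes; a reference
#' panel of 500 individuals and a GWAS cohort of 2000; a tissue study of
#' 60 tumour / 60 NAT / 60 healthy methylation samples.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_panel Reference-panel sample count.
#' @param n_cohort GWAS cohort sample count (must be >= 50).
#' @param m_snps Number of SNPs.
#' @param n_cpgs Number of CpGs.
#' @param n_causal Number of CpGs whose methylation causally affects the
#'   phenotype (and is differentially methylated in tumour tissue).
#' @param n_genes Number of gene models.
#' @param maf_range Target minor-allele-frequency range, inside (0, 0.5).
#' @param ld_decay Adjacent-SNP haplotype copy probability in \[0, 1);
#'   the realised adjacent-dosage correlation is approximately this value.
#' @param snps_per_cpg cis SNPs per CpG weight model.
#' @param h2_meth cis heritability of latent methylation, in (0, 1).
#' @param gamma Per-causal-CpG effect of latent methylation on phenotype.
#' @param dm_effect Tumour - control shift of causal CpGs on the latent
#'   (logit) methylation scale.
#' @param age_effect Latent methylation slope per year of age.
#' @param meth_noise Latent methylation residual sd in the tissue study.
#' @param batch_effect Standard deviation of the per-CpG technical batch
#'   offsets; samples are assigned to two random batches cross-cutting the
#'   biological groups and a random 30 percent of CpGs are shifted per
#'   batch. Large enough by default that the batch axes dominate the PCA,
#'   as technical variation does on real arrays.
#' @param n_tumour,n_nat,n_healthy Tissue-study group sizes.
#' @param n_outliers Planted outlier samples (large global latent shift).
#' @param outlier_shift Latent shift applied to planted outliers.
#' @param missing_rate Fraction of methylation entries set missing.
#' @param de_log2fc log2 fold change injected into genes linked to causal
#'   CpGs (sign coupled to the CpG's methylation direction).
#' @param nb_dispersion Negative-binomial dispersion of expression counts.
#' @param mediation_effect Tumour-only slope of log2 expression on the
#'   linked CpG's beta value (the planted interaction).
#' @param age_range Sampling range of ages in years.
#' @param genome_length Chromosome length in bp.
#' @param block_size LD-block tile width in bp.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_panel = 500L, n_cohort = 2000L,
                       m_snps = 200L, n_cpgs = 40L, n_causal = 8L,
                       n_genes = 30L,
                       maf_range = c(0.1, 0.4), ld_decay = 0.2,
                       snps_per_cpg = 3L, h2_meth = 0.3,
                       gamma = 0.3, dm_effect = 0.15,
                       age_effect = 0.005, meth_noise = 0.2,
                       batch_effect = 0.4,
                       n_tumour = 60L, n_nat = 60L, n_healthy = 60L,
                       n_outliers = 2L, outlier_shift = 3,
                       missing_rate = 0.02,
                       de_log2fc = 1, nb_dispersion = 0.1,
                       mediation_effect = 8,
                       age_range = c(30, 80),
                       genome_length = 2e6, block_size = 5e4) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_panel >= 1, cfg$m_snps >= 1, cfg$n_cpgs >= 1,
            cfg$n_genes >= 1, cfg$n_causal <= cfg$n_cpgs)
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1) {
    abort("ld_decay must lie in [0, 1).")
  }
  if (cfg$h2_meth <= 0 || cfg$h2_meth >= 1) abort("h2_meth must lie in (0, 1).")
  if (cfg$nb_dispersion <= 0) abort("nb_dispersion must be > 0.")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] >= 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    abort("maf_range must satisfy 0 < lo <= hi < 0.5.")
  }
  structure(cfg, class = "sim_config")
}

# Haplotype copy-process: allele j copied from allele j-1 with probability
# theta, else drawn fresh at its target frequency. Marginal frequencies are
# exponentially smoothed mixtures of the targets (hence stay inside the
# target range); adjacent correlation ~= theta.
sim_haplotypes <- function(n_hap, freq, theta) {
  m <- length(freq)
  h <- matrix(0L, n_hap, m)
  h[, 1] <- rbinom(n_hap, 1L, freq[1])
  if (m > 1) {
    for (j in 2:m) {
      fresh <- rbinom(n_hap, 1L, freq[j])
      copy <- runif(n_hap) < theta
      h[, j] <- ifelse(copy, h[, j - 1], fresh)
    }
  }
  h
}

sim_genotypes <- function(n, freq, theta) {
  sim_haplotypes(n, freq, theta) + sim_haplotypes(n, freq, theta)
}

#' Simulate a reference LD panel
#'
#' Generates diploid alt-allele dosages for `m_snps` SNPs on one chromosome
#' under a first-order haplotype copy process: adjacent SNPs share an allele
#' with probability `ld_decay`, yielding adjacent-dosage correlation close
#' to `ld_decay`; target minor-allele frequencies are drawn uniformly from
#' `maf_range` and positions uniformly over the genome. Allele pairs are
#' always one purine-like of \{A, T\} with one of \{C, G\}, so no SNP is
#' strand-ambiguous.
#'
#' @param cfg A [sim_config()].
#' @return A [ref_panel()] with the generator state attached (attribute
#'   `generator`) so that GWAS cohorts can be drawn from the same process.
#' @export
simulate_panel <- function(cfg) {
  set.seed(cfg$seed + 101L)
  m <- cfg$m_snps
  pos <- sort(sample.int(cfg$genome_length, m))
  freq <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  at <- sample(c("A", "T"), m, replace = TRUE)
  cg <- sample(c("C", "G"), m, replace = TRUE)
  swap <- runif(m) < 0.5
  ref <- ifelse(swap, cg, at)
  alt <- ifelse(swap, at, cg)
  d <- sim_genotypes(cfg$n_panel, freq, cfg$ld_decay)
  snps <- tibble(snp_id = sprintf("rs%05d", seq_len(m)),
                 chrom = "1", pos = as.integer(pos),
                 ref_allele = ref, alt_allele = alt)
  colnames(d) <- snps$snp_id
  rownames(d) <- sprintf("P%04d", seq_len(cfg$n_panel))
  out <- ref_panel(d, snps)
  # generator frequencies aligned with retained (non-monomorphic) SNPs
  attr(out, "generator") <- list(freq = freq[match(out$snps$snp_id, snps$snp_id)],
                                 snp_id = out$snps$snp_id,
                                 theta = cfg$ld_decay)
  out
}

#' Simulate gene models, CpG positions and LD blocks
#'
#' Lays out non-overlapping gene models (three exons, UTRs, one in six
#' non-coding) evenly across the chromosome, tiles the chromosome with LD
#' blocks, and places CpGs so that every annotation category (exonic,
#' intronic, 5'/3'-UTR, splicing, upstream, downstream, intergenic,
#' ncRNA exonic/intronic) is represented.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `annotation_set`: `genes` (tibble), `exons`
#'   (tibble of `gene_id`, `start`, `end`), `blocks` (tibble), `cpgs`
#'   (tibble of `cpg_id`, `chrom`, `pos`, `true_category`, `gene_id`).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed + 202L)
  gene_width <- 8000
  margin <- 5e4
  span <- cfg$genome_length - 2 * margin
  if (span < cfg$n_genes * gene_width) abort("Genome too short to pack genes.")
  gap <- floor((span - cfg$n_genes * gene_width) / max(1, cfg$n_genes))
  starts <- margin + (seq_len(cfg$n_genes) - 1) * (gene_width + gap)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  coding <- seq_len(cfg$n_genes) %% 6 != 0
  genes <- tibble(
    gene_id = sprintf("GENE%03d", seq_len(cfg$n_genes)),
    chrom = "1", strand = strand,
    tx_start = as.integer(starts),
    tx_end = as.integer(starts + gene_width - 1),
    cds_start = as.integer(ifelse(coding, starts + 200, NA)),
    cds_end = as.integer(ifelse(coding, starts + gene_width - 201, NA)),
    coding = coding
  )
  exons <- tidyr::crossing(gene_id = genes$gene_id, exon = 1:3) %>%
    left_join(select(genes, "gene_id", "tx_start"), by = "gene_id") %>%
    mutate(start = .data$tx_start + c(0L, 3000L, 7000L)[.data$exon],
           end = .data$tx_start + c(999L, 3999L, 7999L)[.data$exon]) %>%
    select("gene_id", "exon", "start", "end")

  nb <- ceiling(cfg$genome_length / cfg$block_size)
  blocks <- tibble(
    block_id = sprintf("LD%03d", seq_len(nb)),
    chrom = "1",
    start = as.integer((seq_len(nb) - 1) * cfg$block_size + 1),
    end = as.integer(pmin(seq_len(nb) * cfg$block_size, cfg$genome_length))
  )

  categories <- c("exonic", "intronic", "UTR5", "UTR3", "splicing",
                  "upstream", "downstream", "intergenic",
                  "ncRNA_exonic", "ncRNA_intronic")
  coding_ids <- genes$gene_id[genes$coding]
  nc_ids <- genes$gene_id[!genes$coding]
  if (!length(nc_ids)) abort("Need at least one non-coding gene (n_genes >= 6).")

  place <- function(cat, g) {
    s <- genes$tx_start[genes$gene_id == g]
    e <- genes$tx_end[genes$gene_id == g]
    str <- genes$strand[genes$gene_id == g]
    switch(cat,
      exonic = s + 500L,
      ncRNA_exonic = s + 500L,
      intronic = s + 2000L,
      ncRNA_intronic = s + 2000L,
      UTR5 = if (str == "+") s + 100L else e - 100L,
      UTR3 = if (str == "+") e - 100L else s + 100L,
      splicing = s + 1001L,           # first intron base next to exon 1 end
      upstream = if (str == "+") s - 500L else e + 500L,
      downstream = if (str == "+") e + 500L else s - 500L,
      intergenic = e + floor(gap / 2)
    )
  }

  cat_cycle <- rep(categories, length.out = cfg$n_cpgs)
  cod_i <- 0L; nc_i <- 0L
  rows <- purrr::map(seq_len(cfg$n_cpgs), function(i) {
    cat <- cat_cycle[i]
    if (cat %in% c("ncRNA_exonic", "ncRNA_intronic")) {
      nc_i <<- nc_i %% length(nc_ids) + 1L
      g <- nc_ids[nc_i]
    } else {
      cod_i <<- cod_i %% length(coding_ids) + 1L
      g <- coding_ids[cod_i]
    }
    tibble(cpg_id = sprintf("cg%06d", i), chrom = "1",
           pos = as.integer(place(cat, g)),
           true_category = cat,
           gene_id = if (cat == "intergenic") NA_character_ else g)
  }) %>% bind_rows()

  structure(list(genes = genes, exons = exons, blocks = blocks, cpgs = rows),
            class = "annotation_set")
}

#' Simulate cis-meQTL weight models
#'
#' Each CpG receives `snps_per_cpg` distinct cis SNPs (within 1 Mb of its
#' position) with Gaussian raw weights, rescaled so that the genetic score
#' `w . g` has variance `h2_meth` in the reference panel; the latent
#' methylation model is `M = w . g + e` with residual variance
#' `1 - h2_meth`, so the cis heritability equals `h2_meth` by construction.
#'
#' @param panel A [simulate_panel()] result.
#' @param cpgs CpG tibble from [simulate_annotation()].
#' @param cfg A [sim_config()].
#' @return List with `weights` (a `weight_tbl`) and `truth` (tibble of
#'   per-entry true weights, identical here since weights are assigned).
#' @export
simulate_weight_models <- function(panel, cpgs, cfg) {
  set.seed(cfg$seed + 303L)
  snps <- panel$snps
  entries <- purrr::map(seq_len(nrow(cpgs)), function(i) {
    cp <- cpgs[i, ]
    cis <- which(abs(snps$pos - cp$pos) <= 1e6)
    if (length(cis) < cfg$snps_per_cpg) {
      abort(sprintf("CpG %s has only %d cis SNP(s); %d requested.",
                    cp$cpg_id, length(cis), cfg$snps_per_cpg))
    }
    pick <- sample(cis, cfg$snps_per_cpg)
    w <- rnorm(cfg$snps_per_cpg)
    g <- panel$dosage[, pick, drop = FALSE] %*% w
    w <- w * sqrt(cfg$h2_meth) / sd(g)
    tibble(unit_id = cp$cpg_id, unit_chrom = cp$chrom, unit_pos = cp$pos,
           snp_id = snps$snp_id[pick],
           effect_allele = snps$alt_allele[pick],
           other_allele = snps$ref_allele[pick],
           weight = as.numeric(w),
           snp_pos = snps$pos[pick])
  }) %>% bind_rows()
  weights <- as_weight_tbl(entries, cis_window = 1e6)
  list(weights = weights, truth = entries)
}

#' Simulate GWAS summary statistics
#'
#' Draws a cohort of `n_cohort` genotypes from the panel's generative
#' process, builds latent methylation `M_c = w_c . g + e_c` for every CpG,
#' a continuous liability `y = sum(gamma_c * M_c) + eps` over the causal
#' CpGs, and computes per-SNP marginal least-squares `beta`, `se` and `p`
#' on the cohort. The individual-level cohort (genotypes, phenotype,
#' latent methylation) is attached as attribute `cohort` for oracle
#' comparisons.
#'
#' @param panel A [simulate_panel()] result (generator attribute required).
#' @param weights A `weight_tbl` from [simulate_weight_models()].
#' @param cfg A [sim_config()].
#' @param causal Optional tibble with `cpg_id` and `gamma` columns naming
#'   the causal CpGs and their liability effects; by default `n_causal`
#'   CpGs are sampled and given effect `gamma` with alternating sign.
#' @return List with `gwas` (a `gwas_tbl`, cohort attached as attribute
#'   `cohort`) and `truth` (the causal tibble plus per-SNP expected
#'   marginal effects through the causal scores).
#' @export
simulate_gwas <- function(panel, weights, cfg, causal = NULL) {
  if (cfg$n_cohort < 50) abort("n_cohort must be >= 50.")
  gen <- attr(panel, "generator")
  if (is.null(gen)) abort("Panel lacks generator state; use simulate_panel().")
  set.seed(cfg$seed + 404L)
  cpg_ids <- unique(weights$unit_id)
  if (is.null(causal)) {
    ids <- sample(cpg_ids, min(cfg$n_causal, length(cpg_ids)))
    causal <- tibble(cpg_id = ids,
                     gamma = cfg$gamma * rep_len(c(1, -1), length(ids)))
  }
  n <- cfg$n_cohort
  G <- sim_genotypes(n, gen$freq, gen$theta)
  colnames(G) <- gen$snp_id

  M <- matrix(0, n, length(cpg_ids), dimnames = list(NULL, cpg_ids))
  for (cp in cpg_ids) {
    wc <- weights[weights$unit_id == cp, ]
    score <- G[, wc$snp_id, drop = FALSE] %*% wc$weight
    M[, cp] <- score + rnorm(n, sd = sqrt(1 - cfg$h2_meth))
  }
  y <- rnorm(n)
  if (nrow(causal)) {
    present <- causal$cpg_id %in% cpg_ids
    y <- y + M[, causal$cpg_id[present], drop = FALSE] %*% causal$gamma[present]
  }
  y <- as.numeric(y)
  gwas <- marginal_gwas(G, y, panel)
  attr(gwas, "cohort") <- list(G = G, y = y, M = M)
  list(gwas = gwas, truth = causal)
}

# Per-SNP marginal least-squares summary statistics on an individual-level
# cohort (genotypes G, phenotype y), in the panel's allele frame.
marginal_gwas <- function(G, y, panel) {
  n <- length(y)
  xc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- as.numeric(crossprod(xc, yc))
  syy <- sum(yc^2)
  bhat <- sxy / sxx
  sig2 <- pmax((syy - bhat * sxy) / (n - 2), 0)
  se <- sqrt(sig2 / sxx)
  tval <- bhat / se
  pval <- 2 * pt(-abs(tval), df = n - 2)
  idx <- match(colnames(G), panel$snps$snp_id)
  as_gwas_tbl(tibble(
    snp_id = colnames(G),
    chrom = panel$snps$chrom[idx],
    pos = panel$snps$pos[idx],
    effect_allele = panel$snps$alt_allele[idx],
    other_allele = panel$snps$ref_allele[idx],
    eaf = unname(colMeans(G) / 2),
    beta = unname(bhat), se = unname(se),
    p = unname(pmax(pval, .Machine$double.xmin)),
    n = n
  ), source = "marginal_gwas")
}

#' Simulate a tumour / NAT / healthy methylation study
#'
#' Beta values arise from a latent-Gaussian model squashed through the
#' logistic function: per-CpG baseline, a tumour-only shift of `dm_effect`
#' (signed per causal CpG) on the latent scale, an age slope, a per-group
#' batch shift on a random 30 percent of CpGs, Gaussian noise, planted
#' outlier samples (global latent shift) and ~`missing_rate` missing
#' entries.
#'
#' @param cpgs CpG tibble from [simulate_annotation()].
#' @param cfg A [sim_config()].
#' @param causal Optional tibble with `cpg_id` and `dm_sign` (+1 / -1); by
#'   default `n_causal` CpGs sampled with alternating sign.
#' @return List with `meth` (an `omics_mat`: `values` CpG x sample beta
#'   matrix, `meta` sample tibble) and `truth` (causal tibble, planted
#'   outlier ids, missing mask count).
#' @export
simulate_methylation_study <- function(cpgs, cfg, causal = NULL) {
  set.seed(cfg$seed + 505L)
  if (is.null(causal)) {
    ids <- sample(cpgs$cpg_id, min(cfg$n_causal, nrow(cpgs)))
    causal <- tibble(cpg_id = ids,
                     dm_sign = rep_len(c(1, -1), length(ids)))
  }
  groups <- rep(c("tumour", "NAT", "healthy"),
                c(cfg$n_tumour, cfg$n_nat, cfg$n_healthy))
  ns <- length(groups)
  meta <- tibble(sample_id = sprintf("M%03d", seq_len(ns)),
                 sample_type = groups,
                 age = runif(ns, cfg$age_range[1], cfg$age_range[2]))
  m <- nrow(cpgs)
  baseline <- rnorm(m, 0, 0.8)
  dm <- numeric(m)
  ci <- match(causal$cpg_id, cpgs$cpg_id)
  dm[ci] <- causal$dm_sign * cfg$dm_effect

  latent <- matrix(baseline, m, ns) +
    outer(dm, as.numeric(groups == "tumour")) +
    outer(rep(cfg$age_effect, m), meta$age - mean(cfg$age_range)) +
    matrix(rnorm(m * ns, sd = cfg$meth_noise), m, ns)
  # technical batches cross-cut the biological groups (as plates/scanners
  # do), so the PC covariates can absorb them without absorbing the
  # sample-type effect
  batch <- sample(c("b1", "b2"), ns, replace = TRUE)
  meta$batch <- batch
  for (b in unique(batch)) {
    hit <- runif(m) < 0.3
    latent[hit, batch == b] <- latent[hit, batch == b] +
      rnorm(sum(hit), sd = cfg$batch_effect)
  }
  outliers <- character(0)
  if (cfg$n_outliers > 0) {
    oi <- sample(ns, cfg$n_outliers)
    latent[, oi] <- latent[, oi] + cfg$outlier_shift
    outliers <- meta$sample_id[oi]
  }
  beta <- stats::plogis(latent)
  dimnames(beta) <- list(cpgs$cpg_id, meta$sample_id)
  n_missing <- 0L
  if (cfg$missing_rate > 0) {
    mask <- runif(m * ns) < cfg$missing_rate
    beta[mask] <- NA_real_
    n_missing <- sum(mask)
  }
  meth <- structure(list(values = beta, meta = meta), class = "omics_mat")
  list(meth = meth,
       truth = list(causal = causal, outliers = outliers,
                    n_missing = n_missing))
}

#' Simulate a gene-expression count study
#'
#' Negative-binomial counts for tumour and NAT samples matched to the
#' methylation study. Genes hosting causal CpGs receive a tumour log2 fold
#' change of `de_log2fc` whose sign opposes the CpG's methylation
#' direction (hypomethylated CpG, upregulated gene), plus a tumour-only
#' interaction slope of `mediation_effect` log2 units per unit beta of the
#' linked CpG. Library sizes vary over x0.5 - x2.
#'
#' @param ann An `annotation_set`.
#' @param meth_study Result of [simulate_methylation_study()].
#' @param cfg A [sim_config()].
#' @return List with `expr` (an `omics_mat` of integer counts over tumour
#'   and NAT samples) and `truth` (per-gene DE status, injected lfc and
#'   linked CpG).
#' @export
simulate_expression <- function(ann, meth_study, cfg) {
  set.seed(cfg$seed + 606L)
  meta <- filter(meth_study$meth$meta, .data$sample_type %in% c("tumour", "NAT"))
  tumour <- meta$sample_type == "tumour"
  ng <- nrow(ann$genes)
  genes <- ann$genes$gene_id

  causal <- meth_study$truth$causal
  links <- ann$cpgs %>%
    filter(.data$cpg_id %in% causal$cpg_id, !is.na(.data$gene_id)) %>%
    distinct(.data$gene_id, .keep_all = TRUE) %>%
    left_join(causal, by = "cpg_id")

  lfc <- setNames(numeric(ng), genes)
  lfc[links$gene_id] <- -links$dm_sign * cfg$de_log2fc
  linked_cpg <- setNames(rep(NA_character_, ng), genes)
  linked_cpg[links$gene_id] <- links$cpg_id

  base <- runif(ng, 3, 8)
  sf <- 2^runif(nrow(meta), -1, 1)
  beta <- meth_study$meth$values[, meta$sample_id, drop = FALSE]

  counts <- matrix(0L, ng, nrow(meta),
                   dimnames = list(genes, meta$sample_id))
  for (gi in seq_len(ng)) {
    log2mu <- base[gi] + lfc[gi] * tumour
    cp <- linked_cpg[gi]
    if (!is.na(cp)) {
      b <- beta[cp, ]
      b[is.na(b)] <- median(b, na.rm = TRUE)
      # centred within tumour so the interaction adds no mean shift and the
      # group fold change stays at 2^lfc
      log2mu <- log2mu + cfg$mediation_effect * (b - mean(b[tumour])) * tumour
    }
    mu <- 2^log2mu * sf
    counts[gi, ] <- rnbinom(nrow(meta), mu = mu, size = 1 / cfg$nb_dispersion)
  }
  expr <- structure(list(values = counts, meta = meta), class = "omics_mat")
  list(expr = expr,
       truth = tibble(gene_id = genes, true_lfc = unname(lfc),
                      is_de = lfc != 0, linked_cpg = unname(linked_cpg)))
}

#' Simulate a complete study
#'
#' Wires all generators together with one shared causal CpG set: annotation
#' and CpG placement, reference panel, weight models, GWAS summary
#' statistics (liability mediated through causal-CpG methylation), the
#' tissue methylation study (same causal CpGs, methylation direction equal
#' to the liability effect sign) and the expression study (genes of causal
#' CpGs differentially expressed, sign opposing methylation).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_study` with elements `cfg`, `annotation`,
#'   `panel`, `weights`, `gwas`, `meth`, `expr` and `truth` (causal CpGs
#'   with `gamma` and `dm_sign`, true weights, gene DE truth, outliers).
#' @export
simulate_study <- function(cfg = sim_config()) {
  ann <- simulate_annotation(cfg)
  panel <- simulate_panel(cfg)
  wm <- simulate_weight_models(panel, ann$cpgs, cfg)
  set.seed(cfg$seed + 700L)
  ids <- sample(ann$cpgs$cpg_id, min(cfg$n_causal, nrow(ann$cpgs)))
  signs <- rep_len(c(1, -1), length(ids))
  causal <- tibble(cpg_id = ids, gamma = cfg$gamma * signs, dm_sign = signs)
  gw <- simulate_gwas(panel, wm$weights, cfg,
                      causal = select(causal, "cpg_id", "gamma"))
  ms <- simulate_methylation_study(ann$cpgs, cfg,
                                   causal = select(causal, "cpg_id", "dm_sign"))
  ex <- simulate_expression(ann, ms, cfg)
  structure(list(cfg = cfg, annotation = ann, panel = panel,
                 weights = wm$weights, gwas = gw$gwas,
                 meth = ms$meth, expr = ex$expr,
                 truth = list(causal = causal,
                              weights = wm$truth,
                              genes = ex$truth,
                              outliers = ms$truth$outliers)),
            class = "sim_study")
}

#' Write every simulated input in its on-disk text format
#'
#' Writes the GWAS table, weight models, panel (dosage + SNP map), beta
#' matrix with sample metadata, counts, gene models, LD blocks (BED,
#' 0-based half-open) and truth tables into a directory, exercising every
#' loader format the package accepts.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gwas(study$gwas, p("gwas.tsv"))
  write_results(study$weights, p("weights.tsv"))
  write_panel(study$panel, p("panel.tsv"))
  meth <- as_tibble(study$meth$values, rownames = "cpg_id")
  readr::write_tsv(meth, p("meth_beta.tsv"), progress = FALSE)
  write_results(study$meth$meta, p("meth_meta.tsv"))
  counts <- as_tibble(study$expr$values, rownames = "gene_id")
  readr::write_tsv(counts, p("expr_counts.tsv"), progress = FALSE)
  write_results(study$expr$meta, p("expr_meta.tsv"))
  write_results(study$annotation$genes, p("genes.tsv"))
  write_results(study$annotation$exons, p("exons.tsv"))
  bed <- mutate(study$annotation$blocks, start = .data$start - 1L)
  readr::write_tsv(select(bed, "chrom", "start", "end", "block_id"),
                   p("blocks.bed"), col_names = FALSE, progress = FALSE)
  write_results(study$annotation$cpgs, p("cpgs.tsv"))
  write_results(study$truth$causal, p("truth_causal.tsv"))
  write_results(study$truth$genes, p("truth_genes.tsv"))
  invisible(vapply(c("gwas.tsv", "weights.tsv", "panel.tsv", "meth_beta.tsv",
                     "meth_meta.tsv", "expr_counts.tsv", "expr_meta.tsv",
                     "genes.tsv", "exons.tsv", "blocks.bed", "cpgs.tsv",
                     "truth_causal.tsv", "truth_genes.tsv"), p, character(1)))
}
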