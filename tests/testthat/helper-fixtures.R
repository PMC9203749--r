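# Shared fixtures, built in code. Heavy objects are cached per session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# the reference synthetic study used across modules
default_study <- function(seed = 7) {
  cached(paste0("study", seed), simulate_study(sim_config(seed = seed)))
}

tiny_gwas <- function() {
  as_gwas_tbl(tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3"),
    chrom = "1", pos = c(100L, 200L, 300L),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.2, 0.4, 0.3),
    beta = c(0.1, -0.2, 0.05),
    se = c(0.02, 0.05, 0.04),
    p = c(1e-6, 6e-5, 0.2),
    n = 1000
  ))
}

# exact binomial tails by direct summation over the pmf -- the independent
# oracle used against binom_enrich()
binom_tail_oracle <- function(k, n, p0, side) {
  pmf <- dbinom(0:n, n, p0)
  switch(side,
         greater = sum(pmf[(k + 1):(n + 1)]),
         less = sum(pmf[1:(k + 1)]),
         two.sided = sum(pmf[pmf <= (1 + 1e-7) * pmf[k + 1]]))
}

# forward stepwise multiple regression on individual-level data -- the
# oracle for the summary-level conditional scan
stepwise_lm_oracle <- function(G, y, p_entry = 0.05, r2_cap = 0.9) {
  sel <- integer(0)
  repeat {
    rem <- setdiff(seq_len(ncol(G)), sel)
    if (length(sel)) {
      ok <- vapply(rem, function(j) {
        max(cor(G[, j], G[, sel, drop = FALSE])^2) <= r2_cap
      }, logical(1))
      rem <- rem[ok]
    }
    if (!length(rem)) break
    ps <- vapply(rem, function(j) {
      X <- G[, c(sel, j), drop = FALSE]
      sm <- summary(lm(y ~ X))$coefficients
      sm[nrow(sm), 4]
    }, numeric(1))
    if (min(ps) >= p_entry) break
    sel <- c(sel, rem[which.min(ps)])
  }
  colnames(G)[sel]
}
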