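# shared fixture builders and independent oracles

# minimal single-trait parent table: one genotype column of values per rep
toy_parent_table <- function(values, genotypes, year = 2019L, trait = "Ca") {
  stopifnot(length(values) %% length(genotypes) == 0)
  b <- length(values) / length(genotypes)
  tibble::tibble(
    genotype = rep(genotypes, each = b),
    generation = "parent",
    female = NA_character_, male = NA_character_,
    year = year, rep = rep(seq_len(b), length(genotypes)),
    trait = trait, value = values
  )
}

# the packaged balanced 2x2 example: genotypes A (10, 12) and B (20, 21)
toy_2x2 <- function() toy_parent_table(c(10, 12, 20, 21), c("A", "B"))

# balanced two-way random layout: a genotypes x b replicates
random_balanced_layout <- function(a, b, sig_g, sig_r, sig_e, mu = 20) {
  g <- rnorm(a, 0, sqrt(sig_g))
  r <- rnorm(b, 0, sqrt(sig_r))
  e <- rnorm(a * b, 0, sqrt(sig_e))
  toy_parent_table(
    mu + rep(g, each = b) + rep(r, a) + e,
    sprintf("G%02d", seq_len(a))
  )
}

# independent oracle: expected-mean-squares (ANOVA) estimators for the
# balanced two-way random model; equal REML when all components interior
anova_ems_estimates <- function(tab) {
  y <- tab$value
  g <- factor(tab$genotype)
  r <- factor(tab$rep)
  a <- nlevels(g)
  b <- nlevels(r)
  gm <- mean(y)
  msg <- b * sum((tapply(y, g, mean) - gm)^2) / (a - 1)
  msr <- a * sum((tapply(y, r, mean) - gm)^2) / (b - 1)
  sse <- sum((y - ave(y, g) - ave(y, r) + gm)^2)
  mse <- sse / ((a - 1) * (b - 1))
  c(genotype = (msg - mse) / b, replicate = (msr - mse) / a, residual = mse)
}

# independent REML log-likelihood evaluator for the balanced two-way model
# (direct dense-matrix formula, no shared code with the fitting engine)
reml_loglik_2way <- function(tab, sig_g, sig_r, sig_e) {
  y <- tab$value
  n <- length(y)
  Zg <- outer(tab$genotype, unique(tab$genotype), "==") * 1
  Zr <- outer(tab$rep, unique(tab$rep), "==") * 1
  V <- sig_g * tcrossprod(Zg) + sig_r * tcrossprod(Zr) + sig_e * diag(n)
  X <- matrix(1, n)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% crossprod(X, Vi)
  -0.5 * (determinant(V)$modulus[1] + log(XtViX[1, 1]) +
            drop(crossprod(y, P %*% y)))
}

# small hybrid-only one-year simulation for combining-ability tests
small_hybrid_sim <- function(seed, n_f = 6, n_m = 6, n_cross = 24,
                             var_gca_f = 8, var_gca_m = 4, var_sca = 6,
                             resid = 0.5, reps = 2) {
  cfg <- sim_config(
    n_females = n_f, n_males = n_m, n_crosses = n_cross,
    years = "2019", reps = reps, mu = 25,
    var_gca_f = var_gca_f, var_gca_m = var_gca_m, var_sca = var_sca,
    var_year = 0, var_gca_f_by_year = 0, var_gca_m_by_year = 0,
    var_sca_by_year = 0,
    resid_var_by_year = c("2019" = resid), seed = seed
  )
  simulate_ncii(cfg, parents = FALSE)
}

# absolute-difference expectation for comparisons against rounded printed
# values (testthat's tolerance is relative)
expect_near <- function(object, expected, tol) {
  testthat::expect_lt(abs(object - expected), tol)
}
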