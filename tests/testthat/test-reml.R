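test_that("balanced 2x2 example reproduces the closed-form estimates", {
  fit <- fit_reml(toy_2x2(), ncii_model("model1"))
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(unname(est["genotype"]), 45.0, tolerance = 1e-8)
  expect_equal(unname(est["replicate"]), 1.0, tolerance = 1e-8)
  expect_equal(unname(est["residual"]), 0.25, tolerance = 1e-8)
  expect_equal(fit$mu_hat, 15.75, tolerance = 1e-8)
  expect_true(fit$converged)

  # independent oracle: the restricted likelihood is maximised there
  ll_hat <- reml_loglik_2way(toy_2x2(), 45, 1, 0.25)
  expect_equal(fit$reml_loglik, ll_hat, tolerance = 1e-6)
  for (bump in list(c(1.2, 1, 1), c(1, 1.5, 1), c(1, 1, 1.3),
                    c(0.8, 1, 1), c(1, 0.6, 1), c(1, 1, 0.7))) {
    expect_lt(reml_loglik_2way(toy_2x2(), 45 * bump[1], 1 * bump[2],
                               0.25 * bump[3]), ll_hat)
  }
})

test_that("REML equals ANOVA estimators on randomized balanced layouts", {
  withr::local_seed(202)
  done <- 0
  while (done < 8) {
    tab <- random_balanced_layout(sample(4:8, 1), sample(3:5, 1),
                                  sig_g = 6, sig_r = 2, sig_e = 1)
    ems <- anova_ems_estimates(tab)
    if (any(ems <= 0)) next # oracle only valid for interior solutions
    done <- done + 1
    fit <- fit_reml(tab, ncii_model("model1"))
    est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
    expect_equal(unname(est[names(ems)]), unname(ems),
                 tolerance = 1e-6)
  }
})

test_that("engine agrees with lme4 on an unbalanced combining-ability fit", {
  sim <- small_hybrid_sim(seed = 31)
  fit <- fit_reml(sim$table, ncii_model("model5"))
  lf <- lme4::lmer(
    value ~ (1 | female) + (1 | male) + (1 | female:male) + (1 | rep),
    data = sim$table, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- setNames(vc$vcov, vc$grp)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(unname(est["gca_f"]), unname(ref["female"]), tolerance = 1e-4)
  expect_equal(unname(est["gca_m"]), unname(ref["male"]), tolerance = 1e-4)
  expect_equal(unname(est["sca"]), unname(ref["female:male"]),
               tolerance = 1e-4)
  expect_equal(unname(est["residual"]), unname(ref["Residual"]),
               tolerance = 1e-4)
})

test_that("constant response sits at the boundary with mu = value", {
  tab <- toy_parent_table(rep(5, 8), c("A", "B"))
  fit <- fit_reml(tab, ncii_model("model1"))
  expect_equal(fit$mu_hat, 5)
  expect_true(all(tidy(fit)$estimate == 0))
  expect_true(fit$converged)
})

test_that("estimates are invariant to row permutation and label changes", {
  withr::local_seed(77)
  tab <- random_balanced_layout(6, 3, sig_g = 5, sig_r = 1, sig_e = 0.8)
  fit <- fit_reml(tab, ncii_model("model1"))
  perm <- tab[sample(nrow(tab)), ]
  fit_p <- fit_reml(perm, ncii_model("model1"))
  expect_equal(tidy(fit_p)$estimate, tidy(fit)$estimate, tolerance = 1e-9)
  relab <- tab
  relab$genotype <- paste0("zz_", relab$genotype)
  fit_r <- fit_reml(relab, ncii_model("model1"))
  expect_equal(tidy(fit_r)$estimate, tidy(fit)$estimate, tolerance = 1e-9)
})

test_that("BLUPs centre near zero on balanced designs and adjusted means
           reproduce an independent MME solve", {
  fit <- fit_reml(toy_2x2(), ncii_model("model1"))
  b <- fit$blups$genotype
  expect_lt(abs(sum(b$blup)), 1e-8 * diff(range(toy_2x2()$value)))
  am <- adjusted_means(fit, "genotype")
  expect_equal(mean(am$adjusted_mean), fit$mu_hat, tolerance = 1e-8)

  # independent Henderson mixed-model-equation solve at the estimates
  tab <- toy_2x2()
  y <- tab$value
  Zg <- outer(tab$genotype, sort(unique(tab$genotype)), "==") * 1
  Zr <- outer(tab$rep, sort(unique(tab$rep)), "==") * 1
  W <- cbind(1, Zg, Zr)
  sg <- 45; sr <- 1; se <- 0.25
  C <- crossprod(W) / se + diag(c(0, rep(1 / sg, 2), rep(1 / sr, 2)))
  sol <- solve(C, crossprod(W, y) / se)
  expect_equal(am$adjusted_mean, sol[1] + sol[2:3], tolerance = 1e-6)
  expect_true(all(b$pev > 0))
  # PEV from the inverse coefficient matrix
  expect_equal(b$pev, diag(solve(C))[2:3], tolerance = 1e-6)
})

test_that("adjusted_means rejects unknown terms", {
  fit <- fit_reml(toy_2x2(), ncii_model("model1"))
  expect_error(adjusted_means(fit, "gca_f"), "no BLUPs")
})

test_that("likelihood-ratio test uses the boundary mixture", {
  # replicate means exactly equal: replicate variance hits the boundary and
  # dropping the term leaves the restricted likelihood unchanged
  tab <- toy_parent_table(c(10, 12, 21, 19), c("A", "B"))
  full <- fit_reml(tab, ncii_model("model1"))
  red <- fit_reml(tab, drop_term(ncii_model("model1"), "replicate"))
  lrt <- lrt_variance(full, red)
  expect_equal(lrt$statistic, 0, tolerance = 1e-6)
  expect_equal(lrt$p, 1)

  # mixture quantile: statistic 2.706 gives p = 0.05
  f1 <- full; f1$reml_loglik <- -10
  f0 <- red; f0$reml_loglik <- -10 - 2.706 / 2
  expect_equal(lrt_variance(f1, f0)$p, 0.05, tolerance = 1e-3)

  # reversed nesting is rejected
  expect_error(lrt_variance(red, full), "nest")
})

test_that("blup_ttest follows the normal reference", {
  expect_equal(blup_ttest(0, 1)$p, 1)
  expect_identical(blup_ttest(0, 1)$stars, "")
  expect_equal(blup_ttest(1.959964, 1)$p, 0.05, tolerance = 1e-5)
  expect_error(blup_ttest(1, 0), "positive")
  expect_error(blup_ttest(1, -2), "positive")
})

test_that("across-year model separates per-year residual variances", {
  cfg <- sim_config(
    n_females = 6, n_males = 6, n_crosses = 30, reps = 2,
    var_gca_f = 6, var_gca_m = 3, var_sca = 4, var_year = 2,
    var_gca_f_by_year = 1, var_gca_m_by_year = 1, var_sca_by_year = 2,
    resid_var_by_year = c("2019" = 0.3, "2020" = 3), seed = 14
  )
  sim <- simulate_ncii(cfg, parents = FALSE)
  fit <- fit_reml(sim$table, ncii_model("model6"))
  expect_true(fit$converged)
  res <- setNames(fit$residual$estimate, fit$residual$group)
  expect_lt(res[["2019"]], res[["2020"]])
  expect_equal(unname(res[["2019"]]), 0.3, tolerance = 0.25)
  expect_equal(unname(res[["2020"]]), 3, tolerance = 1.2)
})
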