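test_that("heterosis percentages follow the definition", {
  expect_equal(heterosis_pct(12, 10), 20)
  expect_equal(heterosis_pct(10, 10), 0)
  expect_equal(heterosis_pct(2, 10), -80)
  expect_error(heterosis_pct(5, 0), "positive")
  expect_error(heterosis_pct(5, -1), "positive")
})

test_that("heterosis table computes MP/BP and skips incomplete crosses", {
  pm <- tibble::tibble(level = c("F1", "M1"), adjusted_mean = c(10, 20))
  hm <- tibble::tibble(female = "F1", male = "M1", adjusted_mean = 18)
  ht <- build_heterosis_table(pm, hm)
  expect_equal(ht$mp, 15)
  expect_equal(ht$bp, 20)
  expect_equal(ht$mph, 20)
  expect_equal(ht$bph, -10)

  # F1 equal to the best parent: BPH 0, MPH >= 0
  hm2 <- tibble::tibble(female = "F1", male = "M1", adjusted_mean = 20)
  ht2 <- build_heterosis_table(pm, hm2)
  expect_equal(ht2$bph, 0)
  expect_gte(ht2$mph, 0)

  # missing parent mean: cross excluded and reported
  hm3 <- tibble::tibble(female = c("F1", "F9"), male = "M1",
                        adjusted_mean = c(18, 22))
  ht3 <- build_heterosis_table(pm, hm3)
  expect_identical(nrow(ht3), 1L)
  expect_identical(attr(ht3, "excluded")$missing_parent, "F9")
})

test_that("BPH never exceeds MPH for positive distinct parents", {
  withr::local_seed(15)
  for (i in 1:50) {
    pf <- runif(1, 5, 40)
    pm_ <- runif(1, 5, 40)
    f1 <- runif(1, 1, 60)
    pm <- tibble::tibble(level = c("F1", "M1"), adjusted_mean = c(pf, pm_))
    hm <- tibble::tibble(female = "F1", male = "M1", adjusted_mean = f1)
    ht <- build_heterosis_table(pm, hm)
    if (abs(pf - pm_) > 1e-9) expect_lt(ht$bph, ht$mph)
  }
})

test_that("pooled range equals a brute-force scan and ignores ordering", {
  t1 <- tibble::tibble(female = "a", male = "b", f1 = 1, p_f = 1, p_m = 1,
                       mp = 1, bp = 1, mph = c(-3, 7), bph = c(-9, 2))
  expect_equal(unname(pooled_heterosis_range(t1)), c(-9, 7))
  single <- t1[1, ]; single$mph <- 5; single$bph <- 5
  expect_equal(unname(pooled_heterosis_range(single)), c(5, 5))
  # permutation invariance and equality with a direct scan over all entries
  sets <- list(t1, t1[sample(nrow(t1)), ])
  brute <- range(c(t1$mph, t1$bph))
  for (s in sets) expect_equal(unname(pooled_heterosis_range(s)), brute)
  expect_error(pooled_heterosis_range(t1[0, ]), "no heterosis")
})

test_that("combining-ability tables carry BLUPs, tests and ranks", {
  sim <- small_hybrid_sim(seed = 41)
  fit <- fit_reml(sim$table, ncii_model("model5"))
  ca <- combining_ability_tables(fit)
  expect_setequal(unique(ca$gca$role), c("female", "male"))
  expect_identical(nrow(ca$sca), nrow(sim$design$crosses))
  expect_true(all(ca$gca$pev > 0))
  # ranks are a permutation within each role
  fr <- ca$gca$rank[ca$gca$role == "female"]
  expect_setequal(fr, seq_along(fr))
  # stars agree with p
  expect_identical(ca$gca$stars, p_stars(ca$gca$p, ns = ""))

  # genotype-model fit has no combining-ability terms
  tabp <- toy_2x2()
  fitp <- fit_reml(tabp, ncii_model("model1"))
  expect_error(combining_ability_tables(fitp), "model5 or model6")
})

test_that("top-ranked female is the true best combiner when GCA dominates", {
  hits <- 0
  n_sims <- 20
  for (s in seq_len(n_sims)) {
    sim <- small_hybrid_sim(seed = 500 + s, var_gca_f = 50, var_gca_m = 1,
                            var_sca = 1, resid = 0.25)
    fit <- fit_reml(sim$table, ncii_model("model5"))
    ca <- combining_ability_tables(fit)
    top_est <- ca$gca$parent[ca$gca$role == "female" & ca$gca$rank == 1]
    top_true <- names(which.max(sim$effects$gca_f))
    if (identical(top_est, top_true)) hits <- hits + 1
  }
  expect_gt(hits / n_sims, 0.8)
})
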