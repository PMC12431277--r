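test_that("spearman correlation handles monotone and tied series", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(3, 2, 1))$rho, -1)
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$p, 0)

  # midrank oracle: ranks of (1,2,2,4) are (1, 2.5, 2.5, 4)
  sc <- spearman_cor(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(sc$rho, 3 / sqrt(10), tolerance = 1e-10)
  # and the t-approximation p agrees with cor.test's asymptotic path
  ref <- suppressWarnings(
    cor.test(c(1, 2, 2, 4), c(1, 3, 2, 4), method = "spearman",
             exact = FALSE)
  )
  expect_equal(sc$rho, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(sc$p, ref$p.value, tolerance = 1e-8)

  expect_error(spearman_cor(1:3, 1:4), "length")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  # zero-variance series is undefined, not zero
  expect_true(is.na(spearman_cor(c(2, 2, 2), 1:3)$rho))
})

test_that("spearman is invariant under strictly monotone transforms", {
  withr::local_seed(88)
  x <- rnorm(40)
  y <- 0.6 * x + rnorm(40)
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, base)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, base)
  expect_equal(spearman_cor(rank(x), y)$rho, base)
})

test_that("correlation panels align keys and report the full pair set", {
  sim <- small_hybrid_sim(seed = 61)
  fit <- fit_reml(sim$table, ncii_model("model5"))
  ca <- combining_ability_tables(fit)
  gca <- dplyr::transmute(ca$gca, parent = parent, trait = "Ca",
                          year = "2019", gca = blup)
  sca <- dplyr::transmute(ca$sca, female = female, male = male,
                          trait = "Ca", year = "2019", sca = blup)
  # construct heterosis input where F1 is a monotone function of SCA
  het <- dplyr::transmute(
    ca$sca, female = female, male = male, trait = "Ca", year = "2019",
    f1 = 100 + 3 * blup, mph = 2 * blup, bph = 2 * blup - 1
  )
  perf <- tibble::tibble(
    parent = unique(gca$parent), trait = "Ca", year = "2019",
    per_se = seq_along(unique(gca$parent))
  )
  pan <- correlation_panels(perf, gca, sca, het)
  expect_identical(nrow(pan), 9L)
  expect_true(all(abs(pan$rho) <= 1))
  expect_equal(pan$rho[pan$pair == "r(F1, SCA)"], 1)
  expect_equal(pan$rho[pan$pair == "r(SCA, MPH)"], 1)

  # sGCA is the exact sum of the two parental GCA BLUPs
  gmap <- setNames(gca$gca, gca$parent)
  sgca <- gmap[sca$female] + gmap[sca$male]
  r_direct <- spearman_cor(het$f1, unname(sgca))$rho
  expect_equal(pan$rho[pan$pair == "r(F1, sGCA)"], r_direct)

  # misaligned keys are an error that names the offender
  expect_error(
    correlation_panels(perf, gca, sca[-1, ], het),
    "misalignment"
  )
})

test_that("trait correlation matrices are symmetric with unit diagonal", {
  withr::local_seed(99)
  d <- tidyr::expand_grid(genotype = sprintf("G%02d", 1:15),
                          trait = c("Ca", "Mg", "Zn"))
  d$value <- rnorm(nrow(d), 20, 4)
  d$value[d$trait == "Mg"] <- d$value[d$trait == "Ca"] * 0.2 +
    rnorm(15, 0, 0.5)
  m <- trait_cor_matrix(d, "genotype", "value")
  expect_equal(m$rho, t(m$rho))
  expect_equal(unname(diag(m$rho)), rep(1, 3))
  expect_gt(m$rho["Ca", "Mg"], 0.5)
  # degenerate trait: undefined, not zero
  d2 <- d
  d2$value[d2$trait == "Zn"] <- 7
  m2 <- trait_cor_matrix(d2, "genotype", "value")
  expect_true(is.na(m2$rho["Ca", "Zn"]))
  expect_equal(m2$rho["Ca", "Mg"], m$rho["Ca", "Mg"])
})
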