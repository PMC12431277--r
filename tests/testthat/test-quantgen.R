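test_that("additive and dominance variances follow the Design II expectations", {
  gv <- genetic_variances(27.75, 6.69, 25.68)
  expect_equal(gv$sigma2_A, 68.88)
  expect_equal(gv$sigma2_D, 102.72)
  expect_equal(genetic_variances(0, 0, 0), list(sigma2_A = 0, sigma2_D = 0))
  gv2 <- genetic_variances(0.73, 1.09, 7.52)
  expect_equal(gv2$sigma2_A, 3.64)
  expect_equal(gv2$sigma2_D, 30.08)
  expect_error(genetic_variances(-1, 0, 0), "nonnegative")
})

test_that("phenotypic variance composes genotypic and residual parts", {
  expect_equal(phenotypic_variance(68.87, 102.7, 0.48, 2), 171.81)
  expect_equal(phenotypic_variance(3, 7, 0, 2), 10)
  expect_equal(phenotypic_variance(3.64, 30.06, 0.29, 2), 33.845)
  expect_error(phenotypic_variance(1, 1, 1, 0), ">= 1")
})

test_that("heritabilities land on the reported values", {
  expect_near(broad_h2_single_year(62.33, 4.11, 2), 0.97, 0.01)
  expect_equal(broad_h2_single_year(0, 1, 2), 0)
  expect_near(broad_h2_single_year(58.38, 0.48, 2), 0.9959, 1e-4)

  expect_near(broad_h2_across_years(5.97, 7.95, 3.46, 2, 2), 0.55, 0.01)
  expect_near(broad_h2_across_years(2.65, 35.84, 3.09, 2, 2), 0.12, 0.01)
  expect_equal(broad_h2_across_years(3.7, 0, 0, 2, 2), 1)

  nh <- narrow_h2_set(27.75, 6.69, 25.68, 0.48, 2)
  expect_near(nh$h2, 0.40, 0.01)
  expect_near(nh$h2_F, 0.65, 0.01)
  expect_near(nh$h2_M, 0.16, 0.01)
  nh_k <- narrow_h2_set(0.73, 1.09, 7.52, 0.29, 2)
  expect_near(nh_k$h2, 0.11, 0.01)
  # symmetry: no dominance, equal GCA, no residual
  nh_s <- narrow_h2_set(2, 2, 0, 0, 2)
  expect_equal(nh_s$h2, 1)
  expect_equal(nh_s$h2_F, nh_s$h2_M)
})

test_that("degree of dominance uses the square-root form", {
  expect_near(degree_of_dominance(68.88, 102.72), 1.73, 0.01)
  expect_near(degree_of_dominance(3.64, 30.06), 4.07, 0.01)
  expect_equal(degree_of_dominance(2, 1), 1) # additive-dominance boundary
  expect_error(degree_of_dominance(0, 1), "undefined")
  # monotone in both arguments
  expect_gt(degree_of_dominance(3, 10), degree_of_dominance(3, 8))
  expect_lt(degree_of_dominance(4, 10), degree_of_dominance(3, 10))
})

test_that("predictability ratio matches the reported cells", {
  expect_near(predictability_ratio(27.75, 6.69, 25.68), 0.57, 0.01)
  expect_near(predictability_ratio(5.16, 0.16, 5.98), 0.47, 0.01)
  expect_equal(predictability_ratio(3, 1, 0), 1)
  expect_error(predictability_ratio(0, 0, 0), "undefined")
})

test_that("genetic advance reproduces the reported gains", {
  # parents: single-year genotype model variance and mean
  H2p <- broad_h2_single_year(62.33, 4.11, 2)
  gap <- genetic_advance(H2p, 62.33 + 4.11 / 2, 31.34)
  expect_near(gap$GAM, 51.06, 0.1)
  # hybrids: same construction from the hybrid genotype model
  H2h <- broad_h2_single_year(58.38, 0.48, 2)
  gah <- genetic_advance(H2h, 58.38 + 0.48 / 2, 29.32)
  expect_near(gah$GAM, 53.57, 0.1)
  expect_equal(genetic_advance(0, 4, 10)$GA, 0)
  expect_error(genetic_advance(0.5, 4, 0), "nonzero")
})

test_that("derived statistics are mutually consistent on reported columns", {
  # recompute a full column from its variance components and compare
  cols <- list(
    # var_gca_f, var_gca_m, var_sca, resid, h2, D, PR
    ca2019 = c(27.75, 6.69, 25.68, 0.48, 0.40, 1.73, 0.57),
    ca2020 = c(1.40, 1.78, 5.53, 0.84, 0.22, 2.64, 0.36),
    p2019 = c(1.50, 0.67, 2.16, 0.16, 0.33, 1.99, 0.50),
    cu2019 = c(5.16, 0.16, 5.98, 2.29, 0.30, 2.12, 0.47)
  )
  for (cc in cols) {
    nh <- narrow_h2_set(cc[1], cc[2], cc[3], cc[4], 2)
    gv <- genetic_variances(cc[1], cc[2], cc[3])
    expect_near(nh$h2, cc[5], 0.02)
    expect_near(degree_of_dominance(gv$sigma2_A, gv$sigma2_D), cc[6], 0.02)
    expect_near(predictability_ratio(cc[1], cc[2], cc[3]), cc[7], 0.02)
  }
})

test_that("genetic_summary assembles every statistic coherently", {
  s <- genetic_summary(
    var_gca_f = 27.75, var_gca_m = 6.69, var_sca = 25.68, resid = 0.48,
    r = 2, mean = 29.32, sigma2_G = 58.38, resid_G = 0.48
  )
  expect_equal(s$sigma2_A, 68.88)
  expect_near(s$h2, 0.40, 0.01)
  expect_near(s$GAM, 53.57, 0.1)
  expect_true(s$predictability_ratio >= 0 && s$predictability_ratio <= 1)
  expect_true(s$h2 >= 0 && s$h2 <= 1 && s$H2 >= 0 && s$H2 <= 1)
})
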