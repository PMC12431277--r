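#' Additive and dominance genetic variance from combining-ability variances
#'
#' In a North Carolina Design II with unrelated inbred parents the additive
#' genetic variance is twice the sum of the female and male GCA variances,
#' and the dominance variance is four times the SCA variance.
#'
#' @param var_gca_f,var_gca_m Female and male GCA variance components.
#' @param var_sca SCA variance component.
#' @return A named list with `sigma2_A` and `sigma2_D`.
#' @export
#' @examples
#' genetic_variances(27.75, 6.69, 25.68)
genetic_variances <- function(var_gca_f, var_gca_m, var_sca) {
  .assert_nonneg(var_gca_f = var_gca_f, var_gca_m = var_gca_m,
                 var_sca = var_sca)
  list(sigma2_A = 2 * (var_gca_f + var_gca_m), sigma2_D = 4 * var_sca)
}

#' Phenotypic variance on an entry-mean basis
#'
#' `sigma2_P = sigma2_A + sigma2_D + resid / r`, the phenotypic variance of
#' entry means over `r` replicates with genotypic variance decomposed into
#' additive and dominance parts.
#'
#' @param sigma2_A,sigma2_D Additive and dominance variances.
#' @param resid Residual variance.
#' @param r Number of replicates (>= 1).
#' @export
phenotypic_variance <- function(sigma2_A, sigma2_D, resid, r) {
  .assert_nonneg(sigma2_A = sigma2_A, sigma2_D = sigma2_D, resid = resid)
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  sigma2_A + sigma2_D + resid / r
}

#' Broad-sense heritability, single-year
#'
#' `H2 = sigma2_G / (sigma2_G + resid / r)` on an entry-mean basis.
#'
#' @param sigma2_G Genotypic variance.
#' @param resid Residual variance.
#' @param r Number of replicates.
#' @export
#' @examples
#' broad_h2_single_year(62.33, 4.11, 2) # 0.97
broad_h2_single_year <- function(sigma2_G, resid, r) {
  .assert_nonneg(sigma2_G = sigma2_G, resid = resid)
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  den <- sigma2_G + resid / r
  if (den == 0) stop("zero phenotypic variance", call. = FALSE)
  sigma2_G / den
}

#' Broad-sense heritability, across years
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_GxY / n + resid / (n r))` for a
#' trial repeated over `n` years with `r` replicates per year.
#'
#' @param sigma2_G Genotypic variance.
#' @param sigma2_GxY Genotype-by-year interaction variance.
#' @param resid Residual variance.
#' @param n Number of years.
#' @param r Number of replicates per year.
#' @export
#' @examples
#' broad_h2_across_years(5.97, 7.95, 3.46, 2, 2) # 0.55
broad_h2_across_years <- function(sigma2_G, sigma2_GxY, resid, n, r) {
  .assert_nonneg(sigma2_G = sigma2_G, sigma2_GxY = sigma2_GxY, resid = resid)
  if (n < 1 || r < 1) stop("n and r must be >= 1", call. = FALSE)
  den <- sigma2_G + sigma2_GxY / n + resid / (n * r)
  if (den == 0) stop("zero phenotypic variance", call. = FALSE)
  sigma2_G / den
}

#' Narrow-sense heritabilities from combining-ability components
#'
#' Overall narrow-sense heritability `h2 = sigma2_A / sigma2_P`, plus its
#' parent-specific analogues `h2_F = 4 var_gca_f / sigma2_P` and
#' `h2_M = 4 var_gca_m / sigma2_P`, with `sigma2_P` from
#' [phenotypic_variance()].
#'
#' @inheritParams genetic_variances
#' @param resid Residual variance.
#' @param r Number of replicates.
#' @return Named list `h2`, `h2_F`, `h2_M`, `sigma2_P`.
#' @export
#' @examples
#' narrow_h2_set(27.75, 6.69, 25.68, 0.48, 2) # h2 = 0.40
narrow_h2_set <- function(var_gca_f, var_gca_m, var_sca, resid, r) {
  gv <- genetic_variances(var_gca_f, var_gca_m, var_sca)
  s2p <- phenotypic_variance(gv$sigma2_A, gv$sigma2_D, resid, r)
  if (s2p == 0) stop("zero phenotypic variance", call. = FALSE)
  list(
    h2 = gv$sigma2_A / s2p,
    h2_F = 4 * var_gca_f / s2p,
    h2_M = 4 * var_gca_m / s2p,
    sigma2_P = s2p
  )
}

#' Average degree of dominance
#'
#' `D = sqrt(2 sigma2_D / sigma2_A)`; values above one indicate
#' overdominance.
#'
#' @param sigma2_A Additive variance (> 0).
#' @param sigma2_D Dominance variance.
#' @export
#' @examples
#' degree_of_dominance(68.88, 102.72) # 1.73
degree_of_dominance <- function(sigma2_A, sigma2_D) {
  .assert_nonneg(sigma2_A = sigma2_A, sigma2_D = sigma2_D)
  if (any(sigma2_A == 0)) {
    stop("degree of dominance undefined when sigma2_A = 0", call. = FALSE)
  }
  sqrt(2 * sigma2_D / sigma2_A)
}

#' Baker's predictability ratio
#'
#' GCA share of the total combining-ability variance,
#' `(var_gca_f + var_gca_m) / (var_gca_f + var_gca_m + var_sca)`;
#' values near one mean hybrid performance is predictable from parental
#' GCA alone.
#'
#' @inheritParams genetic_variances
#' @export
#' @examples
#' predictability_ratio(5.16, 0.16, 5.98) # 0.47
predictability_ratio <- function(var_gca_f, var_gca_m, var_sca) {
  .assert_nonneg(var_gca_f = var_gca_f, var_gca_m = var_gca_m,
                 var_sca = var_sca)
  den <- var_gca_f + var_gca_m + var_sca
  if (any(den == 0)) {
    stop("predictability ratio undefined when all components are zero",
         call. = FALSE)
  }
  (var_gca_f + var_gca_m) / den
}

#' Expected genetic advance under truncation selection
#'
#' `GA = i * H2 * sqrt(sigma2_P)` and `GAM = 100 * GA / mean`, with `i` the
#' standardised selection differential (2.06 at 5% selected). `H2` must be
#' passed at full precision, not rounded for display.
#'
#' @param H2 Broad-sense heritability (unrounded).
#' @param sigma2_P Phenotypic variance.
#' @param mean Population mean (nonzero).
#' @param i Selection intensity constant, default 2.06 (5% selected).
#' @return Named list `GA` (trait units) and `GAM` (percent of the mean).
#' @export
genetic_advance <- function(H2, sigma2_P, mean, i = 2.06) {
  .assert_nonneg(H2 = H2, sigma2_P = sigma2_P)
  if (mean == 0) stop("mean must be nonzero", call. = FALSE)
  GA <- i * H2 * sqrt(sigma2_P)
  list(GA = GA, GAM = 100 * GA / mean)
}

#' Full derived-statistics summary for one trait-by-year analysis
#'
#' Combines the combining-ability variance components with the genotype-
#' model variance into the derived statistics block reported for each
#' trait and year: additive/dominance/phenotypic variance, narrow-sense
#' heritabilities (overall, female, male), broad-sense heritability,
#' degree of dominance, predictability ratio, and genetic advance.
#'
#' Two genotypic-variance conventions coexist: narrow-sense heritability
#' uses `sigma2_A + sigma2_D` (combining-ability decomposition), while
#' broad-sense heritability and genetic advance use the genotype-model
#' variance `sigma2_G` with its own residual, when supplied.
#'
#' @inheritParams narrow_h2_set
#' @param mean Population mean of the trait.
#' @param sigma2_G Genotypic variance from the per-year genotype model
#'   (optional; enables `H2`, `GA`, `GAM`).
#' @param resid_G Residual variance of the genotype model (defaults to
#'   `resid`).
#' @param i Selection intensity constant.
#' @return One-row tibble with all derived statistics.
#' @export
genetic_summary <- function(var_gca_f, var_gca_m, var_sca, resid, r, mean,
                            sigma2_G = NULL, resid_G = resid, i = 2.06) {
  gv <- genetic_variances(var_gca_f, var_gca_m, var_sca)
  nh <- narrow_h2_set(var_gca_f, var_gca_m, var_sca, resid, r)
  D <- if (gv$sigma2_A > 0) degree_of_dominance(gv$sigma2_A, gv$sigma2_D)
       else NA_real_
  PR <- if (var_gca_f + var_gca_m + var_sca > 0)
    predictability_ratio(var_gca_f, var_gca_m, var_sca) else NA_real_
  if (!is.null(sigma2_G)) {
    H2 <- broad_h2_single_year(sigma2_G, resid_G, r)
    s2p_G <- sigma2_G + resid_G / r
    ga <- genetic_advance(H2, s2p_G, mean, i)
  } else {
    H2 <- NA_real_
    ga <- list(GA = NA_real_, GAM = NA_real_)
  }
  tibble::tibble(
    sigma2_A = gv$sigma2_A, sigma2_D = gv$sigma2_D, sigma2_P = nh$sigma2_P,
    h2 = nh$h2, h2_F = nh$h2_F, h2_M = nh$h2_M, H2 = H2,
    degree_of_dominance = D, predictability_ratio = PR,
    GA = ga$GA, GAM = ga$GAM, mean = mean, r = r, i = i
  )
}
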