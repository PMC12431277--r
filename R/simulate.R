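#' Draw an incomplete factorial mating design
#'
#' Samples `n_crosses` female-by-male pairs uniformly without replacement
#' from the full factorial, redrawing until every female and every male
#' appears in at least one cross (guaranteed feasible whenever
#' `n_crosses >= max(n_females, n_males)`).
#'
#' @param n_females,n_males Numbers of female and male lines.
#' @param n_crosses Number of realised crosses,
#'   `<= n_females * n_males`.
#' @param seed Optional integer seed for reproducibility.
#' @return A `mating_design` (see [validate_design()]) with females
#'   `F01, F02, ...` and males `M01, M02, ...`.
#' @export
#' @examples
#' make_incomplete_factorial(12, 14, 118, seed = 1)
make_incomplete_factorial <- function(n_females, n_males, n_crosses,
                                      seed = NULL) {
  stopifnot(n_females >= 1, n_males >= 1, n_crosses >= 1)
  if (n_crosses > n_females * n_males) {
    stop("infeasible: n_crosses exceeds the full factorial", call. = FALSE)
  }
  females <- sprintf("F%02d", seq_len(n_females))
  males <- sprintf("M%02d", seq_len(n_males))
  full <- expand.grid(female = females, male = males,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  local_seed(seed)
  connected <- n_crosses >= max(n_females, n_males)
  repeat {
    idx <- sample.int(nrow(full), n_crosses)
    crosses <- full[idx, ]
    if (!connected) break
    if (length(unique(crosses$female)) == n_females &&
        length(unique(crosses$male)) == n_males) {
      break
    }
  }
  new_mating_design(females, males, crosses)
}

#' Simulation configuration for a Design II trial
#'
#' Collects the genetic architecture and trial layout used by
#' [simulate_ncii()]. The defaults reproduce the study conditions of the
#' motivating calcium dataset: a 12 x 14 factorial with 118 realised
#' crosses and 26 selfed parents, two years, two replicates, and variance
#' magnitudes taken from the across-year combining-ability decomposition
#' (female/male GCA, SCA, their year interactions, year, and per-year
#' residuals). Replicate-within-year variance, which the source tables do
#' not report, defaults to half the residual variance of the corresponding
#' year. For per-trait study configurations see [study_sim_config()].
#'
#' @param n_females,n_males,n_crosses Design dimensions.
#' @param years Character or integer vector of year labels.
#' @param reps Number of replicates per year.
#' @param trait Trait label for the emitted table.
#' @param mu Overall hybrid mean (trait units).
#' @param mu_parent Overall parent mean.
#' @param var_gca_f,var_gca_m,var_sca Combining-ability variances.
#' @param var_year Year variance.
#' @param var_rep_in_year Named (by year) or scalar replicate-within-year
#'   variance; `NULL` uses `resid_var_by_year / 2`.
#' @param var_gca_f_by_year,var_gca_m_by_year,var_sca_by_year
#'   Year-interaction variances of the combining-ability effects.
#' @param resid_var_by_year Named positive vector of residual variances,
#'   one per year.
#' @param parent_resid_var_by_year Residual variances for the selfed
#'   parents; defaults to `resid_var_by_year`.
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_females = 12, n_males = 14, n_crosses = 118,
                       years = c("2019", "2020"), reps = 2, trait = "Ca",
                       mu = 23.45, mu_parent = 24.49,
                       var_gca_f = 5.19, var_gca_m = 2.38, var_sca = 0.36,
                       var_year = 68.70, var_rep_in_year = NULL,
                       var_gca_f_by_year = 9.33, var_gca_m_by_year = 1.79,
                       var_sca_by_year = 15.36,
                       resid_var_by_year = c("2019" = 0.48, "2020" = 0.84),
                       parent_resid_var_by_year = NULL,
                       seed = 1L) {
  years <- as.character(years)
  resid_var_by_year <- .match_years(resid_var_by_year, years, "resid_var_by_year")
  if (any(resid_var_by_year <= 0)) {
    stop("residual variances must be > 0", call. = FALSE)
  }
  if (is.null(var_rep_in_year)) var_rep_in_year <- resid_var_by_year / 2
  var_rep_in_year <- .match_years(var_rep_in_year, years, "var_rep_in_year")
  if (is.null(parent_resid_var_by_year)) {
    parent_resid_var_by_year <- resid_var_by_year
  }
  parent_resid_var_by_year <-
    .match_years(parent_resid_var_by_year, years, "parent_resid_var_by_year")
  .assert_nonneg(
    var_gca_f = var_gca_f, var_gca_m = var_gca_m, var_sca = var_sca,
    var_year = var_year, var_rep_in_year = var_rep_in_year,
    var_gca_f_by_year = var_gca_f_by_year,
    var_gca_m_by_year = var_gca_m_by_year,
    var_sca_by_year = var_sca_by_year
  )
  stopifnot(n_crosses <= n_females * n_males, reps >= 1)
  structure(
    list(
      n_females = n_females, n_males = n_males, n_crosses = n_crosses,
      years = years, reps = reps, trait = trait, mu = mu,
      mu_parent = mu_parent, var_gca_f = var_gca_f, var_gca_m = var_gca_m,
      var_sca = var_sca, var_year = var_year,
      var_rep_in_year = var_rep_in_year,
      var_gca_f_by_year = var_gca_f_by_year,
      var_gca_m_by_year = var_gca_m_by_year,
      var_sca_by_year = var_sca_by_year,
      resid_var_by_year = resid_var_by_year,
      parent_resid_var_by_year = parent_resid_var_by_year,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

.match_years <- function(v, years, what) {
  if (length(v) == 1 && is.null(names(v))) {
    v <- stats::setNames(rep(v, length(years)), years)
  }
  if (is.null(names(v))) names(v) <- years
  if (!all(years %in% names(v))) {
    stop(sprintf("`%s` must name every year", what), call. = FALSE)
  }
  v[years]
}

# Across-year hybrid variance magnitudes and population means used for the
# nine-trait study generator (macro traits g/kg DW, micro traits mg/kg DW).
.study_arch <- tibble::tribble(
  ~trait, ~mu,    ~mu_parent, ~gca_f, ~gca_m, ~sca,   ~gf_y,  ~gm_y,  ~sca_y,  ~year,     ~r2019,  ~r2020,
  "Ca",   23.45,  24.49,      5.19,   2.38,   0.36,   9.33,   1.79,   15.36,   68.70,     0.48,    0.84,
  "K",    34.25,  25.47,      1.29,   1.41,   0.00,   2.37,   0.87,   13.77,   205.55,    0.29,    1.31,
  "Mg",   4.93,   4.99,       0.15,   0.33,   0.00,   0.00,   0.09,   1.10,    2.30,      0.04,    0.06,
  "Na",   0.90,   1.05,       0.01,   0.00,   0.00,   0.01,   0.00,   0.09,    0.004,     0.004,   0.01,
  "P",    9.55,   7.99,       0.40,   0.00,   0.00,   0.51,   0.43,   1.70,    1.25,      0.16,    0.71,
  "Fe",   151.52, 158.25,     91.94,  0.00,   176.06, 338.23, 66.14,  2438.36, 171.38,    412.01,  266.54,
  "Zn",   73.19,  56.07,      56.66,  7.82,   12.61,  216.40, 0.00,   475.39,  1.95,      16.23,   8.28,
  "Cu",   9.66,   10.63,      0.00,   0.10,   0.00,   2.52,   0.00,   6.13,    1.91,      2.29,    0.96,
  "Mn",   192.03, 109.89,     37.53,  39.56,  66.75,  0.00,   300.22, 2854.64, 43916.29,  13.02,   167.40
)

#' Study-condition simulation configuration for one mineral trait
#'
#' Returns a [sim_config()] whose variance magnitudes, means and per-year
#' residuals follow the published study conditions for the requested trait
#' (12 females x 14 males, 118 crosses, two years, two replicates).
#'
#' @param trait One of the nine mineral traits.
#' @param seed Integer master seed.
#' @export
study_sim_config <- function(trait = "Ca", seed = 1L) {
  stopifnot(trait %in% .trait_vocab)
  a <- .study_arch[.study_arch$trait == trait, ]
  sim_config(
    trait = trait, mu = a$mu, mu_parent = a$mu_parent,
    var_gca_f = a$gca_f, var_gca_m = a$gca_m, var_sca = a$sca,
    var_gca_f_by_year = a$gf_y, var_gca_m_by_year = a$gm_y,
    var_sca_by_year = a$sca_y, var_year = a$year,
    resid_var_by_year = c("2019" = a$r2019, "2020" = a$r2020),
    seed = seed
  )
}

# set.seed locally, restoring the caller's RNG state on exit (two frames up
# so helpers can call it on behalf of their caller)
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  withr::defer(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    },
    envir = envir
  )
  set.seed(seed)
  invisible(NULL)
}

#' Simulate a Design II phenotype table with known effects
#'
#' Draws every random term of the across-year combining-ability model —
#' year, replicate within year, female GCA, male GCA, SCA, their year
#' interactions and residual — as independent mean-zero Gaussians with the
#' configured variances, and sums them into hybrid phenotypes. Selfed
#' parents are optionally emitted with genotypic value
#' `mu_parent + 2 * (own GCA)` plus noise, a documented convention that
#' gives synthetic mid-/best-parent heterosis a known structure.
#'
#' @param config A [sim_config()].
#' @param design Optional `mating_design`; drawn with
#'   [make_incomplete_factorial()] from the config dimensions when `NULL`.
#' @param parents Emit selfed-parent phenotypes as well (default `TRUE`).
#' @return A list with `table` (validated phenotype tibble), `effects`
#'   (named list of realised effect vectors) and `design`.
#' @export
simulate_ncii <- function(config, design = NULL, parents = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed)
  if (is.null(design)) {
    design <- make_incomplete_factorial(
      config$n_females, config$n_males, config$n_crosses
    )
  }
  females <- design$females
  males <- design$males
  crosses <- design$crosses
  years <- config$years
  reps <- seq_len(config$reps)

  rnorm_var <- function(n, v, nms = NULL) {
    out <- if (v > 0) stats::rnorm(n, 0, sqrt(v)) else numeric(n)
    if (!is.null(nms)) names(out) <- nms
    out
  }
  cross_id <- paste(crosses$female, crosses$male, sep = ":")
  fy <- as.vector(outer(females, years, paste, sep = ":"))
  my <- as.vector(outer(males, years, paste, sep = ":"))
  cy <- as.vector(outer(cross_id, years, paste, sep = ":"))
  ry <- as.vector(outer(reps, years, paste, sep = ":"))
  rep_var <- rep(config$var_rep_in_year, each = length(reps))

  eff <- list(
    year = rnorm_var(length(years), config$var_year, years),
    rep_in_year = stats::setNames(
      stats::rnorm(length(ry), 0, sqrt(rep_var)), ry
    ),
    gca_f = rnorm_var(length(females), config$var_gca_f, females),
    gca_m = rnorm_var(length(males), config$var_gca_m, males),
    sca = rnorm_var(nrow(crosses), config$var_sca, cross_id),
    gca_f_by_year = rnorm_var(length(fy), config$var_gca_f_by_year, fy),
    gca_m_by_year = rnorm_var(length(my), config$var_gca_m_by_year, my),
    sca_by_year = rnorm_var(length(cy), config$var_sca_by_year, cy)
  )

  grid <- tidyr::expand_grid(
    cross = seq_len(nrow(crosses)), year = years, rep = reps
  )
  f <- crosses$female[grid$cross]
  m <- crosses$male[grid$cross]
  cid <- cross_id[grid$cross]
  resid <- stats::rnorm(
    nrow(grid), 0, sqrt(config$resid_var_by_year[grid$year])
  )
  hyb_value <- config$mu +
    eff$year[grid$year] +
    eff$rep_in_year[paste(grid$rep, grid$year, sep = ":")] +
    eff$gca_f[f] + eff$gca_m[m] + eff$sca[cid] +
    eff$gca_f_by_year[paste(f, grid$year, sep = ":")] +
    eff$gca_m_by_year[paste(m, grid$year, sep = ":")] +
    eff$sca_by_year[paste(cid, grid$year, sep = ":")] +
    resid
  hyb <- tibble::tibble(
    genotype = paste0(f, "x", m), generation = "hybrid",
    female = f, male = m, year = grid$year, rep = grid$rep,
    trait = config$trait, value = unname(hyb_value)
  )

  out <- hyb
  if (parents) {
    par_ids <- c(females, males)
    own_gca <- c(eff$gca_f, eff$gca_m)[par_ids]
    pgrid <- tidyr::expand_grid(parent = par_ids, year = years, rep = reps)
    presid <- stats::rnorm(
      nrow(pgrid), 0, sqrt(config$parent_resid_var_by_year[pgrid$year])
    )
    par_value <- config$mu_parent + 2 * own_gca[pgrid$parent] +
      eff$year[pgrid$year] +
      eff$rep_in_year[paste(pgrid$rep, pgrid$year, sep = ":")] +
      presid
    par <- tibble::tibble(
      genotype = pgrid$parent, generation = "parent",
      female = NA_character_, male = NA_character_,
      year = pgrid$year, rep = pgrid$rep,
      trait = config$trait, value = unname(par_value)
    )
    out <- dplyr::bind_rows(par, hyb)
  }
  # concentrations are nonnegative by contract; truncate the rare negatives
  out$value <- pmax(out$value, 0)
  list(table = validate_phenotype_table(out), effects = eff, design = design)
}

#' Monte-Carlo parameter recovery for the combining-ability model
#'
#' Simulates `n_sims` datasets from a configuration, fits the per-year
#' combining-ability model to one year of each (or the across-year model
#' when `model = "model6"`), and summarises the estimates against the
#' simulation truth.
#'
#' @param config A [sim_config()].
#' @param design Optional fixed `mating_design` shared by all replicates.
#' @param n_sims Number of simulation replicates.
#' @param model `"model5"` (default; first year only) or `"model6"`.
#' @param fitter Fitting function, by default [fit_reml()].
#' @param ... Passed on to `fitter`.
#' @return A list with `summary` (per-component tibble: truth, mean
#'   estimate, bias, RMSE, coverage of estimate +/- 2 SE intervals) and
#'   `estimates` (per-replicate tibble), plus the non-convergence count.
#' @export
parameter_recovery <- function(config, design = NULL, n_sims = 20,
                               model = c("model5", "model6"),
                               fitter = fit_reml, ...) {
  model <- match.arg(model)
  stopifnot(inherits(config, "sim_config"), n_sims >= 1)
  if (is.null(design)) {
    design <- make_incomplete_factorial(
      config$n_females, config$n_males, config$n_crosses, seed = config$seed
    )
  }
  year1 <- config$years[1]
  truth <- c(
    gca_f = config$var_gca_f, gca_m = config$var_gca_m, sca = config$var_sca,
    residual = unname(config$resid_var_by_year[year1])
  )
  n_fail <- 0L
  rows <- purrr::map(seq_len(n_sims), function(s) {
    cfg <- config
    cfg$seed <- config$seed + s
    sim <- simulate_ncii(cfg, design = design, parents = FALSE)
    tab <- sim$table
    if (model == "model5") tab <- tab[tab$year == year1, ]
    fit <- fitter(tab, ncii_model(model), ...)
    if (!fit$converged) n_fail <<- n_fail + 1L
    comp <- tidy(fit)
    comp$sim <- s
    comp
  })
  est <- dplyr::bind_rows(rows)
  est <- est[est$term %in% names(truth), ]
  est$truth <- truth[est$term]
  summary <- dplyr::summarise(
    dplyr::group_by(est, .data$term),
    truth = .data$truth[1],
    mean_estimate = mean(.data$estimate),
    bias = mean(.data$estimate - .data$truth),
    rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
    coverage = mean(
      !is.na(.data$se) & abs(.data$estimate - .data$truth) <= 2 * .data$se
    ),
    .groups = "drop"
  )
  list(summary = summary, estimates = est, n_nonconverged = n_fail)
}
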