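#' Run the full Design II analysis pipeline
#'
#' Orchestrates every stage of the analysis on a phenotype table (or a
#' simulated one): outlier QC, descriptive statistics and
#' parent-vs-hybrid comparisons, per-year genotype and combining-ability
#' fits, across-year fits with heterogeneous residuals, derived
#' quantitative-genetics summaries, combining-ability and heterosis
#' tables, and the Spearman association panels.
#'
#' @param data A validated phenotype table, or `NULL` to simulate from
#'   `sim`.
#' @param sim Optional [sim_config()] used when `data` is `NULL`.
#' @param traits Traits to analyse (default: all present).
#' @param qc Run outlier flagging and drop flagged rows (default `TRUE`).
#' @param alpha Family-wise level for the QC screen.
#' @param across_years Also fit the across-year models 3 and 6 (default
#'   `TRUE` when more than one year is present).
#' @param outdir Optional output directory; when given, results are
#'   written via [write_report()].
#' @param seed Seed forwarded to the simulation config (when simulating).
#' @return A list of class `ncii_results` with elements `data`, `design`,
#'   `qc`, `descriptives`, `population_tests`, `fits` (per trait/year),
#'   `genetic_summary`, `ca_gca`, `ca_sca`, `heterosis`,
#'   `heterosis_range`, `panels`, `across_year`, and `manifest` (stage
#'   log, seed, warnings).
#' @export
run_pipeline <- function(data = NULL, sim = NULL, traits = NULL, qc = TRUE,
                         alpha = 0.05, across_years = NULL, outdir = NULL,
                         seed = NULL) {
  manifest <- list(
    stages = character(), warnings = character(), seed = seed,
    package_version = as.character(utils::packageVersion("nciigen")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  note <- function(stage) manifest$stages <<- c(manifest$stages, stage)
  warn <- function(msg) manifest$warnings <<- c(manifest$warnings, msg)

  if (is.null(data)) {
    if (is.null(sim)) stop("provide `data` or a simulation config `sim`",
                           call. = FALSE)
    if (!is.null(seed)) sim$seed <- as.integer(seed)
    data <- simulate_ncii(sim)$table
    note("simulate")
  }
  data <- validate_phenotype_table(data)
  if (is.null(traits)) traits <- sort(unique(data$trait))
  data <- data[data$trait %in% traits, ]
  design <- validate_design(data)
  years <- sort(unique(data$year))
  if (is.null(across_years)) across_years <- length(years) > 1
  note("validate")

  qc_flags <- NULL
  if (qc) {
    qc_flags <- flag_outliers(data, alpha = alpha)
    if (nrow(qc_flags)) {
      key <- paste(data$genotype, data$year, data$rep, data$trait)
      drop <- key %in% paste(qc_flags$genotype, qc_flags$year, qc_flags$rep,
                             qc_flags$trait)
      data <- data[!drop, ]
      warn(sprintf("QC dropped %d observation(s)", sum(drop)))
    }
    note("qc")
  }

  descr <- descriptive_stats(data)
  pop_tests <- dplyr::bind_rows(
    purrr::map(traits, function(tr) compare_populations(data, tr))
  )
  note("describe")

  slices <- tidyr::expand_grid(trait = traits, year = years)
  per_year <- purrr::pmap(slices, function(trait, year) {
    d <- data[data$trait == trait & data$year == year, ]
    dp <- d[d$generation == "parent", ]
    dh <- d[d$generation == "hybrid", ]
    fit1_p <- fit_reml(dp, ncii_model("model1"))
    fit1_h <- fit_reml(dh, ncii_model("model1"))
    fit5 <- fit_reml(dh, ncii_model("model5"))
    for (f in list(fit1_p, fit1_h, fit5)) {
      if (!f$converged) {
        warn(sprintf("non-convergence: %s %s %s", f$model, trait, year))
      }
    }
    list(trait = trait, year = year, parents_model1 = fit1_p,
         hybrids_model1 = fit1_h, model5 = fit5)
  })
  note("fit_per_year")

  comp <- function(fit, term) {
    e <- fit$components$estimate[fit$components$term == term]
    if (length(e)) e else 0
  }
  gsum <- dplyr::bind_rows(purrr::map(per_year, function(s) {
    f5 <- s$model5
    f1h <- s$hybrids_model1
    f1p <- s$parents_model1
    r <- length(unique(data$rep[data$trait == s$trait &
                                  data$year == s$year]))
    hyb_mean <- f1h$mu_hat
    hyb <- genetic_summary(
      var_gca_f = comp(f5, "gca_f"), var_gca_m = comp(f5, "gca_m"),
      var_sca = comp(f5, "sca"), resid = f5$residual$estimate[1], r = r,
      mean = hyb_mean, sigma2_G = comp(f1h, "genotype"),
      resid_G = f1h$residual$estimate[1]
    )
    H2p <- broad_h2_single_year(comp(f1p, "genotype"),
                                f1p$residual$estimate[1], r)
    gap <- genetic_advance(H2p, comp(f1p, "genotype") +
                             f1p$residual$estimate[1] / r, f1p$mu_hat)
    dplyr::bind_rows(
      dplyr::mutate(hyb, population = "hybrids", .before = 1),
      tibble::tibble(
        population = "parents", H2 = H2p, GA = gap$GA, GAM = gap$GAM,
        mean = f1p$mu_hat, r = r, i = 2.06
      )
    ) |>
      dplyr::mutate(trait = s$trait, year = s$year, .before = 1)
  }))
  note("genetic_summary")

  ca <- purrr::map(per_year, function(s) combining_ability_tables(s$model5))
  ca_gca <- dplyr::bind_rows(purrr::map2(ca, per_year, function(t, s) {
    dplyr::mutate(t$gca, trait = s$trait, year = s$year, .before = 1)
  }))
  ca_sca <- dplyr::bind_rows(purrr::map2(ca, per_year, function(t, s) {
    dplyr::mutate(t$sca, trait = s$trait, year = s$year, .before = 1)
  }))
  note("combining_ability")

  het <- dplyr::bind_rows(purrr::map(per_year, function(s) {
    pmeans <- adjusted_means(s$parents_model1, "genotype")
    hmeans <- adjusted_means(s$hybrids_model1, "genotype")
    hm <- dplyr::inner_join(
      dplyr::distinct(data[data$generation == "hybrid" &
                             data$trait == s$trait, ],
                      .data$genotype, .data$female, .data$male),
      hmeans, by = c(genotype = "level")
    )
    ht <- build_heterosis_table(
      pmeans, hm[c("female", "male", "adjusted_mean")], design
    )
    dplyr::mutate(ht, trait = s$trait, year = s$year, .before = 1)
  }))
  het_range <- pooled_heterosis_range(het)
  note("heterosis")

  parent_perf <- dplyr::bind_rows(purrr::map(per_year, function(s) {
    am <- adjusted_means(s$parents_model1, "genotype")
    tibble::tibble(parent = am$level, trait = s$trait, year = s$year,
                   per_se = am$adjusted_mean)
  }))
  gca_long <- dplyr::transmute(ca_gca, parent = .data$parent,
                               trait = .data$trait, year = .data$year,
                               gca = .data$blup)
  sca_long <- dplyr::transmute(ca_sca, female = .data$female,
                               male = .data$male, trait = .data$trait,
                               year = .data$year, sca = .data$blup)
  panels <- correlation_panels(parent_perf, gca_long, sca_long, het)
  note("correlate")

  across <- NULL
  if (across_years) {
    across <- dplyr::bind_rows(purrr::map(traits, function(tr) {
      d <- data[data$trait == tr, ]
      f3p <- fit_reml(d[d$generation == "parent", ], ncii_model("model3"))
      f3h <- fit_reml(d[d$generation == "hybrid", ], ncii_model("model3"))
      f6 <- fit_reml(d, ncii_model("model6"))
      for (f in list(f3p, f3h, f6)) {
        if (!f$converged) warn(sprintf("non-convergence: %s %s", f$model, tr))
      }
      r <- length(unique(d$rep))
      n_years <- length(unique(d$year))
      h2row <- function(fit, pop) {
        sg <- comp(fit, "genotype")
        sgy <- comp(fit, "genotype:year")
        se <- mean(fit$residual$estimate)
        tibble::tibble(
          trait = tr, population = pop,
          sigma2_G = sg, sigma2_GxY = sgy, sigma2_e = se,
          H2 = broad_h2_across_years(sg, sgy, se, n_years, r)
        )
      }
      dplyr::bind_rows(
        h2row(f3p, "parents"),
        h2row(f3h, "hybrids"),
        dplyr::mutate(tidy(f6), trait = tr, population = "hybrids_model6",
                      .before = 1)
      )
    }))
    note("fit_across_years")
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  results <- structure(
    list(
      data = data, design = design, qc = qc_flags, descriptives = descr,
      population_tests = pop_tests, fits = per_year,
      genetic_summary = gsum, ca_gca = ca_gca, ca_sca = ca_sca,
      heterosis = het, heterosis_range = het_range, panels = panels,
      across_year = across, manifest = manifest
    ),
    class = "ncii_results"
  )
  if (!is.null(outdir)) write_report(results, outdir)
  results
}

#' Write pipeline results to disk
#'
#' Emits the stable CSV/JSON file set for a pipeline run: descriptive
#' statistics, per-year variance components, derived genetic summaries,
#' combining-ability and heterosis tables, association panels, a JSON
#' manifest, and a text summary listing the top-5 GCA parents and top-5
#' SCA crosses per trait.
#'
#' @param results An `ncii_results` object from [run_pipeline()].
#' @param outdir Output directory (created if absent; must be writable).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(results, outdir) {
  if (!inherits(results, "ncii_results") || !length(results$fits)) {
    stop("results are empty or not from run_pipeline()", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir) || file.access(outdir, 2) != 0) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  files <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    readr::write_csv(df, path, progress = FALSE)
    files <<- c(files, path)
  }
  emit(results$descriptives, "descriptive_stats.csv")
  emit(results$population_tests, "population_tests.csv")
  comps <- dplyr::bind_rows(purrr::map(results$fits, function(s) {
    dplyr::bind_rows(
      dplyr::mutate(tidy(s$parents_model1), model = "model1_parents"),
      dplyr::mutate(tidy(s$hybrids_model1), model = "model1_hybrids"),
      dplyr::mutate(tidy(s$model5), model = "model5")
    ) |>
      dplyr::mutate(trait = s$trait, year = s$year, .before = 1)
  }))
  emit(comps, "variance_components_per_year.csv")
  emit(results$genetic_summary, "genetic_summary.csv")
  emit(results$ca_gca, "combining_ability_gca.csv")
  emit(results$ca_sca, "combining_ability_sca.csv")
  emit(results$heterosis, "heterosis.csv")
  emit(results$panels, "correlation_panels.csv")
  if (!is.null(results$across_year)) {
    emit(results$across_year, "across_year_components.csv")
  }
  if (!is.null(results$qc) && nrow(results$qc)) emit(results$qc, "qc_flags.csv")

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(
    c(results$manifest,
      list(heterosis_range = unname(results$heterosis_range),
           files = basename(files))),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  files <- c(files, manifest_path)

  summary_path <- file.path(outdir, "summary.txt")
  con <- file(summary_path, "w")
  on.exit(close(con))
  for (tr in sort(unique(results$ca_gca$trait))) {
    writeLines(sprintf("== %s ==", tr), con)
    g <- results$ca_gca[results$ca_gca$trait == tr, ]
    top_g <- utils::head(g[order(-g$blup), ], 5)
    writeLines("Top-5 parents by GCA:", con)
    writeLines(sprintf("  %s (%s, %s): %.3f %s", top_g$parent, top_g$role,
                       top_g$year, top_g$blup, top_g$stars), con)
    s <- results$ca_sca[results$ca_sca$trait == tr, ]
    top_s <- utils::head(s[order(-s$blup), ], 5)
    writeLines("Top-5 crosses by SCA:", con)
    writeLines(sprintf("  %s x %s (%s): %.3f %s", top_s$female, top_s$male,
                       top_s$year, top_s$blup, top_s$stars), con)
  }
  writeLines(sprintf("Pooled heterosis range: %.1f%% to %.1f%%",
                     results$heterosis_range["min"],
                     results$heterosis_range["max"]), con)
  files <- c(files, summary_path)
  invisible(files)
}

#' @export
print.ncii_results <- function(x, ...) {
  cat("Design II pipeline results:",
      length(unique(x$genetic_summary$trait)), "trait(s),",
      length(unique(x$genetic_summary$year)), "year(s)\n")
  cat("Stages:", paste(x$manifest$stages, collapse = " -> "), "\n")
  cat(sprintf("Pooled heterosis range: %.1f%% to %.1f%%\n",
              x$heterosis_range["min"], x$heterosis_range["max"]))
  if (length(x$manifest$warnings)) {
    cat("Warnings:\n", paste(" -", x$manifest$warnings, collapse = "\n"),
        "\n")
  }
  invisible(x)
}
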