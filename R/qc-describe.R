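#' Flag outlying observations by studentized residuals
#'
#' Quality-control screen in the style recommended for plant-breeding
#' trials: for each trait-by-year (and generation) slice, the per-year
#' genotype model (response ~ genotype + replicate) is fitted, externally
#' studentized residuals are computed, their two-sided t p-values are
#' adjusted by the Holm step-down procedure, and observations significant
#' at family level `alpha` are flagged. Flagging only — removal is the
#' caller's choice.
#'
#' @param data A validated phenotype table.
#' @param model Screening model label; only `"model1"` (genotype +
#'   replicate within trait, year and generation) is defined.
#' @param alpha Family-wise significance level, default 0.05. `alpha = 0`
#'   flags nothing.
#' @return A tibble of flagged rows (`genotype`, `generation`, `year`,
#'   `rep`, `trait`, `value`, `studentized`, `p_holm`) with attributes
#'   `method` and `alpha`.
#' @export
flag_outliers <- function(data, model = "model1", alpha = 0.05) {
  data <- validate_phenotype_table(data)
  model <- match.arg(model, "model1")
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1)
  groups <- dplyr::group_split(
    dplyr::group_by(data, .data$trait, .data$year, .data$generation)
  )
  flags <- lapply(groups, function(g) {
    # rstudent needs at least one residual df beyond the deleted observation
    n_g <- length(unique(g$genotype))
    n_r <- length(unique(g$rep))
    if (nrow(g) - (n_g + n_r - 1) < 3) {
      stop("insufficient data for outlier screening in trait ", g$trait[1],
           ", year ", g$year[1], " (need >= 3 residual df)", call. = FALSE)
    }
    terms <- c(if (n_g > 1) "factor(genotype)", if (n_r > 1) "factor(rep)")
    fit <- stats::lm(stats::reformulate(terms, response = "value"), data = g)
    r <- stats::rstudent(fit)
    df <- stats::df.residual(fit) - 1L
    p <- 2 * stats::pt(abs(r), df = df, lower.tail = FALSE)
    g$studentized <- as.numeric(r)
    g$p_holm <- stats::p.adjust(p, method = "holm")
    g[!is.na(g$p_holm) & g$p_holm < alpha, ]
  })
  out <- dplyr::bind_rows(flags)
  if (!nrow(out)) {
    out <- tibble::tibble(
      genotype = character(), generation = character(), female = character(),
      male = character(), year = integer(), rep = integer(),
      trait = character(), value = double(), studentized = double(),
      p_holm = double()
    )
  }
  out <- out[c("genotype", "generation", "year", "rep", "trait", "value",
               "studentized", "p_holm")]
  attr(out, "method") <- "Holm on externally studentized residuals (model1)"
  attr(out, "alpha") <- alpha
  out
}

#' Descriptive statistics per population and trait
#'
#' Mean, minimum, maximum, standard error of the mean and coefficient of
#' variation for each (generation, trait), computed on the raw observations
#' pooled across years and replicates.
#'
#' @param data A validated phenotype table.
#' @return A tibble with columns `generation`, `trait`, `n`, `mean`, `min`,
#'   `max`, `se` (= sd/sqrt(n)) and `cv` (= 100 sd/mean, in percent).
#' @export
descriptive_stats <- function(data) {
  data <- validate_phenotype_table(data)
  out <- dplyr::summarise(
    dplyr::group_by(data, .data$generation, .data$trait),
    n = dplyr::n(),
    mean = mean(.data$value),
    min = min(.data$value),
    max = max(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    cv = 100 * stats::sd(.data$value) / mean(.data$value),
    .groups = "drop"
  )
  if (any(out$n < 2)) {
    stop("descriptive_stats needs >= 2 observations per (population, trait)",
         call. = FALSE)
  }
  out
}

#' Compare parent and hybrid populations for one trait
#'
#' Tests the difference between the parental and hybrid populations.
#' When both samples pass the Shapiro-Wilk normality test at 0.05 a Welch
#' t-test is used, otherwise the Wilcoxon rank-sum test.
#'
#' @param data A validated phenotype table.
#' @param trait One of the nine mineral traits.
#' @param years Optional year(s) to restrict to; default uses all years.
#' @return A one-row tibble: `trait`, `years`, `test` ("t" or "wilcoxon"),
#'   `statistic`, `p`, `stars`, and the two population means.
#' @export
compare_populations <- function(data, trait, years = NULL) {
  data <- validate_phenotype_table(data)
  stopifnot(trait %in% .trait_vocab)
  d <- data[data$trait == trait, ]
  if (!is.null(years)) d <- d[d$year %in% years, ]
  x <- d$value[d$generation == "parent"]
  y <- d$value[d$generation == "hybrid"]
  if (length(x) < 3 || length(y) < 3) {
    stop("need >= 3 observations in each population", call. = FALSE)
  }
  # shapiro.test caps at n = 5000 and rejects constant input
  normal <- function(v) {
    if (length(v) > 5000) v <- v[seq_len(5000)]
    if (stats::sd(v) == 0) return(TRUE)
    stats::shapiro.test(v)$p.value >= 0.05
  }
  if (normal(x) && normal(y)) {
    ht <- stats::t.test(x, y)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    test <- "wilcoxon"
  }
  tibble::tibble(
    trait = trait,
    years = paste(sort(unique(d$year)), collapse = "+"),
    test = test,
    statistic = unname(ht$statistic),
    p = ht$p.value,
    stars = p_stars(ht$p.value, ns = ""),
    mean_parent = mean(x),
    mean_hybrid = mean(y)
  )
}
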