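#' Mixed-model specifications for Design II analysis
#'
#' Builds one of the four model specifications used throughout the package.
#' All have a single fixed intercept; every other term is random:
#'
#' * `model1` — per-year genotype model: replicate + genotype, single
#'   residual. Fit separately per trait, year and population.
#' * `model3` — across-year genotype model: year + replicate within year +
#'   genotype + genotype x year, heterogeneous per-year residuals.
#' * `model5` — per-year combining-ability model (hybrids only): female
#'   GCA + male GCA + SCA + replicate, single residual.
#' * `model6` — across-year combining-ability model: replicate within
#'   year + year + female GCA + male GCA + SCA + each combining-ability
#'   term x year, heterogeneous per-year residuals.
#'
#' @param name One of `"model1"`, `"model3"`, `"model5"`, `"model6"`.
#' @return An object of class `ncii_model`: list with `name`, `terms`
#'   (ordered random-term labels) and `residual` (`"single"` or
#'   `"by_year"`).
#' @export
ncii_model <- function(name = c("model1", "model3", "model5", "model6")) {
  name <- match.arg(name)
  terms <- switch(name,
    model1 = c("replicate", "genotype"),
    model3 = c("year", "replicate:year", "genotype", "genotype:year"),
    model5 = c("gca_f", "gca_m", "sca", "replicate"),
    model6 = c("replicate:year", "year", "gca_f", "gca_m", "sca",
               "gca_f:year", "gca_m:year", "sca:year")
  )
  residual <- if (name %in% c("model3", "model6")) "by_year" else "single"
  structure(list(name = name, terms = terms, residual = residual),
            class = "ncii_model")
}

#' Drop one random term from a model specification
#'
#' Produces the reduced specification used as the null model of a
#' variance-component likelihood-ratio test.
#'
#' @param spec An `ncii_model`.
#' @param term A random-term label present in `spec$terms`.
#' @export
drop_term <- function(spec, term) {
  stopifnot(inherits(spec, "ncii_model"))
  if (!term %in% spec$terms) {
    stop("term '", term, "' not in model ", spec$name, call. = FALSE)
  }
  spec$terms <- setdiff(spec$terms, term)
  spec$name <- paste0(spec$name, " - ", term)
  spec
}

#' @export
print.ncii_model <- function(x, ...) {
  cat("Design II mixed model ", x$name, "\n",
      "  random: ", paste(x$terms, collapse = " + "), "\n",
      "  residual: ", x$residual, "\n", sep = "")
  invisible(x)
}

# factor builders for each random-term label; `d` holds character columns
.term_factor <- function(term, d) {
  f <- switch(term,
    "replicate" = d$rep,
    "genotype" = d$genotype,
    "year" = d$year,
    "replicate:year" = paste(d$rep, d$year, sep = ":"),
    "genotype:year" = paste(d$genotype, d$year, sep = ":"),
    "gca_f" = d$female,
    "gca_m" = d$male,
    "sca" = paste(d$female, d$male, sep = ":"),
    "gca_f:year" = paste(d$female, d$year, sep = ":"),
    "gca_m:year" = paste(d$male, d$year, sep = ":"),
    "sca:year" = paste(d$female, d$male, d$year, sep = ":"),
    stop("unknown random term: ", term, call. = FALSE)
  )
  factor(f)
}
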