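#' Percent heterosis against a parental reference
#'
#' `100 * (f1 - reference) / reference`; the reference is the mid-parent
#' value for mid-parent heterosis (MPH) or the better parent for
#' best-parent heterosis (BPH). Concentrations are positive, so a
#' nonpositive reference is an error.
#'
#' @param f1 Hybrid adjusted mean(s).
#' @param reference Positive reference value(s), recycled against `f1`.
#' @export
#' @examples
#' heterosis_pct(12, 10) # 20
heterosis_pct <- function(f1, reference) {
  stopifnot(is.numeric(f1), is.numeric(reference))
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("reference must be positive", call. = FALSE)
  }
  100 * (f1 - reference) / reference
}

#' Mid- and best-parent heterosis table
#'
#' Joins hybrid adjusted means with their parents' adjusted means and
#' computes the mid-parent value `MP = (P_f + P_m) / 2`, the best-parent
#' value `BP = max(P_f, P_m)` (all nine minerals are scored
#' "more is better"), and MPH/BPH percentages. Crosses with a missing
#' parent mean are skipped and listed in the `excluded` attribute.
#'
#' @param parent_means Tibble with columns `level` (parent id) and
#'   `adjusted_mean` — e.g. [adjusted_means()] of a parent genotype-model
#'   fit.
#' @param hybrid_means Tibble with columns `female`, `male`,
#'   `adjusted_mean` for each cross.
#' @param design Optional `mating_design` to restrict and validate the
#'   cross set.
#' @return Tibble `female`, `male`, `f1`, `mp`, `bp`, `mph`, `bph`, with
#'   attribute `excluded` (tibble of skipped crosses and the missing
#'   parent).
#' @export
build_heterosis_table <- function(parent_means, hybrid_means, design = NULL) {
  stopifnot(all(c("level", "adjusted_mean") %in% names(parent_means)),
            all(c("female", "male", "adjusted_mean") %in% names(hybrid_means)))
  hm <- tibble::as_tibble(hybrid_means)
  if (!is.null(design)) {
    key <- paste(hm$female, hm$male)
    dkey <- paste(design$crosses$female, design$crosses$male)
    if (!all(key %in% dkey)) {
      stop("hybrid means contain crosses absent from the design",
           call. = FALSE)
    }
  }
  pm <- stats::setNames(parent_means$adjusted_mean, parent_means$level)
  pf <- pm[hm$female]
  pmle <- pm[hm$male]
  missing <- is.na(pf) | is.na(pmle)
  excluded <- tibble::tibble(
    female = hm$female[missing], male = hm$male[missing],
    missing_parent = unname(ifelse(is.na(pf[missing]), hm$female[missing],
                                   hm$male[missing]))
  )
  keep <- !missing
  mp <- (pf[keep] + pmle[keep]) / 2
  bp <- pmax(pf[keep], pmle[keep])
  out <- tibble::tibble(
    female = hm$female[keep], male = hm$male[keep],
    f1 = hm$adjusted_mean[keep],
    p_f = unname(pf[keep]), p_m = unname(pmle[keep]),
    mp = unname(mp), bp = unname(bp),
    mph = heterosis_pct(hm$adjusted_mean[keep], unname(mp)),
    bph = heterosis_pct(hm$adjusted_mean[keep], unname(bp))
  )
  attr(out, "excluded") <- excluded
  out
}

#' Pooled heterosis range
#'
#' Extremes over all MPH and BPH entries of one or more heterosis tables —
#' the "pooled" range across crosses, traits, years and both heterosis
#' definitions.
#'
#' @param tables A heterosis table (from [build_heterosis_table()]) or a
#'   list of them; extra grouping columns are ignored.
#' @return Named numeric vector `c(min = , max = )`, in percent.
#' @export
pooled_heterosis_range <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  vals <- unlist(purrr::map(tables, function(t) c(t$mph, t$bph)))
  if (!length(vals)) stop("no heterosis entries", call. = FALSE)
  c(min = min(vals), max = max(vals))
}

#' Combining-ability tables from a fitted model
#'
#' Assembles the GCA BLUPs of every female and male parent and the SCA
#' BLUPs of every cross from a combining-ability fit, with their
#' prediction-error variances, two-tailed significance (see
#' [blup_ttest()]) and within-role GCA ranks (1 = largest effect).
#'
#' @param fit An `ncii_fit` of `model5` or `model6`.
#' @return A list of class `ca_tables`: `gca` (tibble role/parent/blup/
#'   pev/t/p/stars/rank) and `sca` (tibble female/male/blup/pev/t/p/stars),
#'   plus `trait` and `model`.
#' @export
combining_ability_tables <- function(fit) {
  stopifnot(inherits(fit, "ncii_fit"))
  need <- c("gca_f", "gca_m", "sca")
  if (!all(need %in% names(fit$blups))) {
    stop("fit has no combining-ability terms; use model5 or model6",
         call. = FALSE)
  }
  one_role <- function(term, role) {
    b <- fit$blups[[term]]
    tt <- if (all(b$pev > 0)) blup_ttest(b$blup, b$pev) else
      tibble::tibble(t = rep(NA_real_, nrow(b)), p = NA_real_,
                     stars = NA_character_)
    tibble::tibble(
      role = role, parent = b$level, blup = b$blup, pev = b$pev,
      t = tt$t, p = tt$p, stars = tt$stars,
      rank = rank(-b$blup, ties.method = "min")
    )
  }
  gca <- dplyr::bind_rows(one_role("gca_f", "female"),
                          one_role("gca_m", "male"))
  b <- fit$blups[["sca"]]
  fm <- do.call(rbind, strsplit(b$level, ":", fixed = TRUE))
  tt <- if (all(b$pev > 0)) blup_ttest(b$blup, b$pev) else
    tibble::tibble(t = rep(NA_real_, nrow(b)), p = NA_real_,
                   stars = NA_character_)
  sca <- tibble::tibble(
    female = fm[, 1], male = fm[, 2], blup = b$blup, pev = b$pev,
    t = tt$t, p = tt$p, stars = tt$stars
  )
  structure(list(gca = gca, sca = sca, trait = fit$trait, model = fit$model),
            class = "ca_tables")
}

#' @export
print.ca_tables <- function(x, ...) {
  cat("Combining-ability tables (", x$model, "), trait ", x$trait, "\n",
      sep = "")
  cat("Top parents by GCA:\n")
  top <- dplyr::slice_min(dplyr::group_by(x$gca, .data$role), .data$rank,
                          n = 3, with_ties = FALSE)
  print(as.data.frame(top), row.names = FALSE, digits = 3)
  invisible(x)
}
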