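#' Spearman rank correlation with midrank ties
#'
#' Rank correlation computed as the Pearson correlation of midranks, with
#' the p-value from the t approximation on n - 2 degrees of freedom. A
#' series with zero rank variance yields an undefined (NA) coefficient
#' rather than zero.
#'
#' @param x,y Numeric series of equal length >= 3, finite.
#' @return Named list `rho`, `p`, `n`.
#' @export
#' @examples
#' spearman_cor(1:10, (1:10)^3) # rho = 1, monotone invariance
spearman_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Association panels between performance, combining ability and heterosis
#'
#' For each trait-by-year slice, computes the Spearman correlations that
#' summarise how well combining ability predicts performance and
#' heterosis: r(per se, GCA) over parents, and r(F1, SCA), r(F1, MPH),
#' r(F1, BPH), r(SCA, MPH), r(SCA, BPH), r(F1, sGCA), r(sGCA, MPH),
#' r(sGCA, BPH) over crosses, where sGCA is the exact sum of the two
#' parental GCA BLUPs of each cross.
#'
#' @param parent_perf Tibble `parent`, `trait`, `year`, `per_se` (parent
#'   per-se adjusted means).
#' @param gca Tibble `parent`, `trait`, `year`, `gca` (GCA BLUPs, both
#'   roles).
#' @param sca Tibble `female`, `male`, `trait`, `year`, `sca` (SCA BLUPs).
#' @param het Tibble `female`, `male`, `trait`, `year`, `f1`, `mph`, `bph`
#'   (see [build_heterosis_table()]).
#' @return Long tibble `trait`, `year`, `pair`, `rho`, `p`, `stars`, `n`.
#' @export
correlation_panels <- function(parent_perf, gca, sca, het) {
  stopifnot(
    all(c("parent", "trait", "year", "per_se") %in% names(parent_perf)),
    all(c("parent", "trait", "year", "gca") %in% names(gca)),
    all(c("female", "male", "trait", "year", "sca") %in% names(sca)),
    all(c("female", "male", "trait", "year", "f1", "mph", "bph") %in%
          names(het))
  )
  slices <- dplyr::distinct(het, .data$trait, .data$year)
  out <- purrr::pmap(slices, function(trait, year) {
    tr <- trait; yr <- year
    pp <- parent_perf[parent_perf$trait == tr & parent_perf$year == yr, ]
    gg <- gca[gca$trait == tr & gca$year == yr, ]
    ss <- sca[sca$trait == tr & sca$year == yr, ]
    hh <- het[het$trait == tr & het$year == yr, ]

    panel <- list()
    # parents panel
    joined <- dplyr::inner_join(pp, gg, by = c("parent", "trait", "year"))
    if (nrow(joined) < nrow(pp)) {
      stop("key misalignment: parents without GCA in ", tr, "/", yr, ": ",
           paste(setdiff(pp$parent, joined$parent), collapse = ", "),
           call. = FALSE)
    }
    panel$`r(per se, GCA)` <- spearman_cor(joined$per_se, joined$gca)

    # crosses panel: align heterosis/F1 with SCA and the parental GCA sums
    hs <- dplyr::inner_join(hh, ss, by = c("female", "male", "trait", "year"))
    if (nrow(hs) < nrow(hh)) {
      bad <- dplyr::anti_join(hh, ss, by = c("female", "male"))
      stop("key misalignment: crosses without SCA in ", tr, "/", yr, ": ",
           paste(paste(bad$female, bad$male, sep = "x"), collapse = ", "),
           call. = FALSE)
    }
    gmap <- stats::setNames(gg$gca, gg$parent)
    if (!all(c(hs$female, hs$male) %in% names(gmap))) {
      stop("key misalignment: cross parents without GCA in ", tr, "/", yr,
           call. = FALSE)
    }
    hs$sgca <- unname(gmap[hs$female]) + unname(gmap[hs$male])
    panel$`r(F1, SCA)` <- spearman_cor(hs$f1, hs$sca)
    panel$`r(F1, MPH)` <- spearman_cor(hs$f1, hs$mph)
    panel$`r(F1, BPH)` <- spearman_cor(hs$f1, hs$bph)
    panel$`r(SCA, MPH)` <- spearman_cor(hs$sca, hs$mph)
    panel$`r(SCA, BPH)` <- spearman_cor(hs$sca, hs$bph)
    panel$`r(F1, sGCA)` <- spearman_cor(hs$f1, hs$sgca)
    panel$`r(sGCA, MPH)` <- spearman_cor(hs$sgca, hs$mph)
    panel$`r(sGCA, BPH)` <- spearman_cor(hs$sgca, hs$bph)

    tibble::tibble(
      trait = tr, year = yr, pair = names(panel),
      rho = unname(purrr::map_dbl(panel, "rho")),
      p = unname(purrr::map_dbl(panel, "p")),
      stars = p_stars(unname(purrr::map_dbl(panel, "p"))),
      n = unname(purrr::map_int(panel, "n"))
    )
  })
  dplyr::bind_rows(out)
}

#' Trait-by-trait Spearman correlation matrix
#'
#' Builds the symmetric rank-correlation matrix among traits from a long
#' table of per-unit values (units are parents, crosses, SCA effects or
#' heterosis values, one panel at a time). Pairs are complete-case; traits
#' with zero variance give NA rows/columns, not zeros.
#'
#' @param data Long tibble with a unit key column, a `trait` column, and a
#'   value column.
#' @param unit Name of the unit key column (e.g. `"genotype"` or
#'   `"cross"`).
#' @param value Name of the value column.
#' @return List with matrices `rho`, `p`, `n` (traits x traits).
#' @export
trait_cor_matrix <- function(data, unit, value) {
  stopifnot(all(c(unit, "trait", value) %in% names(data)))
  wide <- tidyr::pivot_wider(
    data[c(unit, "trait", value)],
    names_from = "trait", values_from = dplyr::all_of(value)
  )
  traits <- setdiff(names(wide), unit)
  m <- length(traits)
  rho <- p <- nmat <- matrix(
    NA_real_, m, m, dimnames = list(traits, traits)
  )
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      x <- wide[[traits[i]]]
      y <- wide[[traits[j]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3) next
      sc <- spearman_cor(x[ok], y[ok])
      rho[i, j] <- rho[j, i] <- sc$rho
      p[i, j] <- p[j, i] <- sc$p
      nmat[i, j] <- nmat[j, i] <- sc$n
    }
  }
  list(rho = rho, p = p, n = nmat)
}
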