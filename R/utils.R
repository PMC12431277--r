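#' Significance stars
#'
#' Convert p-values to the conventional `***`/`**`/`*` annotation at the
#' 0.001, 0.01 and 0.05 levels; non-significant values get `"ns"` (or `""`
#' when `ns = ""`).
#'
#' @param p Numeric vector of p-values.
#' @param ns Label used for p >= 0.05 (default `"ns"`).
#' @return Character vector, same length as `p`.
#' @export
#' @examples
#' p_stars(c(0.2, 0.03, 0.004, 2e-5))
p_stars <- function(p, ns = "ns") {
  stopifnot(is.numeric(p))
  out <- rep(ns, length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# mineral vocabulary: macro elements in g/kg DW, micro elements in mg/kg DW
.trait_vocab <- c("Ca", "K", "Mg", "Na", "P", "Fe", "Zn", "Cu", "Mn")
.macro_traits <- c("Ca", "K", "Mg", "Na", "P")

#' Mineral trait vocabulary
#'
#' The nine leaf-mineral traits handled by the package, with their reporting
#' units: macroelements (Ca, K, Mg, Na, P) in g per kg dry weight,
#' microelements (Fe, Zn, Cu, Mn) in mg per kg dry weight.
#'
#' @return A tibble with columns `trait` and `unit`.
#' @export
mineral_traits <- function() {
  tibble::tibble(
    trait = .trait_vocab,
    unit = ifelse(.trait_vocab %in% .macro_traits, "g/kg DW", "mg/kg DW")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.assert_nonneg <- function(..., .allow_zero = TRUE) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop(sprintf("`%s` must be finite numeric", nms[i]), call. = FALSE)
    }
    if (any(v < 0)) {
      stop(sprintf("`%s` must be nonnegative", nms[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
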