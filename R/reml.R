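#' REML variance components and BLUPs for a Design II mixed model
#'
#' Estimates the variance components of one of the [ncii_model()]
#' specifications by restricted maximum likelihood and solves Henderson's
#' mixed-model equations at the optimum for the intercept, the BLUPs of
#' every random level and their prediction-error variances (PEV).
#'
#' The optimiser is a hybrid of expectation-maximisation (EM) steps —
#' monotone in the restricted likelihood and guaranteed to respect the
#' nonnegativity of variance components — and average-information (AI)
#' Newton steps for fast terminal convergence, with step-halving back to EM
#' whenever an AI step would leave the parameter space or decrease the
#' likelihood. Components attracted to the boundary are fixed at zero.
#' Standard errors of the components come from the inverse
#' average-information matrix at the optimum (boundary components are
#' reported with SE 0). The across-year models use one residual variance
#' per year.
#'
#' @param data A validated phenotype table restricted to a single trait;
#'   for `model1`/`model5` also to a single year. `model5`/`model6` use the
#'   hybrid rows only; `model1`/`model3` require a single generation
#'   (filter parents or hybrids first).
#' @param spec An [ncii_model()] specification.
#' @param tol_loglik Relative restricted-log-likelihood convergence
#'   tolerance (default `1e-10`).
#' @param tol_par Absolute parameter-change tolerance relative to the
#'   phenotypic variance (default `1e-8`).
#' @param max_iter Maximum number of iterations (default 200).
#' @param n_em Number of initial plain EM steps before AI updates start.
#' @return An object of class `ncii_fit`: `mu_hat`, `components`
#'   (tibble term/estimate/se), `residual` (tibble group/estimate/se),
#'   `blups` (named list of tibbles level/blup/pev), `reml_loglik`,
#'   `converged`, `n_iter`, `n`, and the model name. Non-convergence is
#'   flagged, not thrown.
#' @seealso [lrt_variance()], [adjusted_means()], [blup_ttest()],
#'   [combining_ability_tables()]
#' @export
fit_reml <- function(data, spec, tol_loglik = 1e-10, tol_par = 1e-8,
                     max_iter = 200L, n_em = 2L) {
  stopifnot(inherits(spec, "ncii_model"))
  data <- validate_phenotype_table(data)
  if (length(unique(data$trait)) != 1) {
    stop("fit one trait at a time", call. = FALSE)
  }
  base_model <- sub(" .*", "", spec$name)
  if (base_model %in% c("model5", "model6")) {
    data <- data[data$generation == "hybrid", ]
    if (!nrow(data)) stop("no hybrid rows", call. = FALSE)
  } else if (length(unique(data$generation)) != 1) {
    stop("model1/model3 expect a single population; filter parents or ",
         "hybrids first", call. = FALSE)
  }
  per_year <- base_model %in% c("model1", "model5")
  if (per_year && length(unique(data$year)) != 1) {
    stop(spec$name, " is a per-year model; filter to one year first",
         call. = FALSE)
  }
  # deterministic row order so estimates are invariant to input permutation
  d <- data[order(data$genotype, data$year, data$rep), ]
  d$rep <- as.character(d$rep)
  d$year <- as.character(d$year)

  y <- d$value
  n <- length(y)
  X <- matrix(1, n, 1)
  facs <- lapply(spec$terms, .term_factor, d = d)
  names(facs) <- spec$terms
  Z <- lapply(facs, function(f) {
    stats::model.matrix(~ 0 + f)
  })
  for (i in seq_along(Z)) colnames(Z[[i]]) <- levels(facs[[i]])
  rgroup <- if (spec$residual == "by_year") factor(d$year) else
    factor(rep("all", n))

  eng <- .reml_engine(y, X, Z, rgroup, tol_loglik, tol_par, max_iter, n_em)

  comp <- tibble::tibble(
    term = spec$terms,
    estimate = eng$theta_u,
    se = eng$se_u
  )
  resid <- tibble::tibble(
    group = levels(rgroup),
    estimate = eng$theta_r,
    se = eng$se_r
  )
  structure(
    list(
      model = spec$name, spec = spec, trait = d$trait[1],
      years = sort(unique(d$year)), n = n,
      mu_hat = eng$mu_hat, components = comp, residual = resid,
      blups = eng$blups, reml_loglik = eng$loglik,
      converged = eng$converged, n_iter = eng$n_iter
    ),
    class = "ncii_fit"
  )
}

# Core REML engine on the P-matrix formulation.
# y: response; X: fixed design (intercept); Z: list of random design
# matrices; rgroup: residual grouping factor.
.reml_engine <- function(y, X, Z, rgroup, tol_loglik, tol_par, max_iter,
                         n_em) {
  n <- length(y)
  k <- length(Z)
  glev <- levels(rgroup)
  ng <- length(glev)
  gidx <- lapply(glev, function(g) which(rgroup == g))
  if (n - ncol(X) < 1) stop("no residual degrees of freedom", call. = FALSE)

  vary <- stats::var(y)
  scale_y <- mean(y)^2 + vary
  if (vary < 1e-12 * scale_y) {
    # degenerate constant response: all components at the boundary
    blups <- lapply(Z, function(Zi) tibble::tibble(
      level = colnames(Zi), blup = 0, pev = 0
    ))
    names(blups) <- names(Z)
    return(list(
      theta_u = rep(0, k), theta_r = rep(0, ng),
      se_u = rep(0, k), se_r = rep(0, ng),
      mu_hat = mean(y), blups = blups, loglik = NA_real_,
      converged = TRUE, n_iter = 0L
    ))
  }

  Q <- lapply(Z, tcrossprod)           # n x n per random term
  q_u <- vapply(Z, ncol, integer(1))   # levels per term
  q_r <- lengths(gidx)
  floor_v <- 1e-10 * vary

  theta <- rep(vary / (k + 1), k + ng) # u components then residual groups
  fixed0 <- rep(FALSE, k)              # random components pinned at zero

  eval_ll <- function(theta) {
    V <- matrix(0, n, n)
    for (i in seq_len(k)) if (theta[i] > 0) V <- V + theta[i] * Q[[i]]
    dg <- numeric(n)
    for (g in seq_len(ng)) dg[gidx[[g]]] <- theta[k + g]
    diag(V) <- diag(V) + pmax(dg, floor_v)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VX <- Vinv %*% X
    XtVX <- crossprod(X, VX)
    XtVXinv <- solve(XtVX)
    P <- Vinv - VX %*% XtVXinv %*% t(VX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    determinant(XtVX, logarithm = TRUE)$modulus[1] +
                    sum(y * Py))
    list(ll = ll, P = P, Py = Py)
  }

  st <- eval_ll(theta)
  if (is.null(st)) stop("initial covariance matrix is singular", call. = FALSE)
  ll <- st$ll
  converged <- FALSE
  iter <- 0L

  trace_quad <- function(st) {
    # tr(P Q_i), y'P Q_i P y and the AI working vectors for every component
    trPQ <- numeric(k + ng)
    quad <- numeric(k + ng)
    Vw <- matrix(0, n, k + ng)
    for (i in seq_len(k)) {
      trPQ[i] <- sum(st$P * Q[[i]])
      u <- crossprod(Z[[i]], st$Py)
      quad[i] <- sum(u^2)
      Vw[, i] <- Z[[i]] %*% u
    }
    dP <- diag(st$P)
    for (g in seq_len(ng)) {
      j <- k + g
      trPQ[j] <- sum(dP[gidx[[g]]])
      quad[j] <- sum(st$Py[gidx[[g]]]^2)
      w <- numeric(n); w[gidx[[g]]] <- st$Py[gidx[[g]]]
      Vw[, j] <- w
    }
    list(trPQ = trPQ, quad = quad, Vw = Vw)
  }

  em_step <- function(theta, tq) {
    qs <- c(q_u, q_r)
    new <- theta + theta^2 / qs * (tq$quad - tq$trPQ)
    pmax(new, 0)
  }

  tq <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    tq <- trace_quad(st)
    score <- -0.5 * (tq$trPQ - tq$quad)
    # random components at zero whose gradient points outward stay pinned
    fixed0 <- theta[seq_len(k)] <= floor_v & score[seq_len(k)] < 0
    free <- c(!fixed0, rep(TRUE, ng))

    theta_new <- NULL
    if (iter > n_em && sum(free) > 0) {
      PVw <- st$P %*% tq$Vw[, free, drop = FALSE]
      AI <- 0.5 * crossprod(tq$Vw[, free, drop = FALSE], PVw)
      delta <- tryCatch(solve(AI, score[free]), error = function(e) NULL)
      if (!is.null(delta)) {
        step <- delta
        for (h in seq_len(12)) {
          # project the Newton step back onto the parameter space
          prop <- theta
          prop[free] <- theta[free] + step
          prop[seq_len(k)] <- pmax(prop[seq_len(k)], 0)
          prop[seq_len(k)][fixed0] <- 0
          prop[k + seq_len(ng)] <- pmax(prop[k + seq_len(ng)], floor_v)
          st_prop <- eval_ll(prop)
          if (!is.null(st_prop) && st_prop$ll >= ll - 1e-10) {
            theta_new <- prop
            st_new <- st_prop
            break
          }
          step <- step / 2
        }
      }
    }
    if (is.null(theta_new)) {
      theta_new <- em_step(theta, tq)
      theta_new[seq_len(k)][fixed0] <- 0
      theta_new[k + seq_len(ng)] <- pmax(theta_new[k + seq_len(ng)], floor_v)
      st_new <- eval_ll(theta_new)
      if (is.null(st_new)) break
    }
    dll <- abs(st_new$ll - ll)
    dpar <- max(abs(theta_new - theta)) / vary
    theta <- theta_new
    ll <- st_new$ll
    st <- st_new
    if (dll < tol_loglik * (abs(ll) + 1) && dpar < tol_par) {
      converged <- TRUE
      break
    }
  }

  # report components at/near the boundary as exact zeros
  theta_u <- theta[seq_len(k)]
  theta_u[theta_u < 1e-7 * vary] <- 0
  theta_r <- theta[k + seq_len(ng)]
  theta_r[theta_r <= floor_v * 1.01] <- 0

  # SEs from the AI matrix over interior components
  se_u <- rep(0, k)
  se_r <- rep(0, ng)
  tq <- trace_quad(st)
  interior <- c(theta_u > 0, theta_r > 0)
  if (any(interior)) {
    PVw <- st$P %*% tq$Vw[, interior, drop = FALSE]
    AI <- 0.5 * crossprod(tq$Vw[, interior, drop = FALSE], PVw)
    AIinv <- tryCatch(solve(AI), error = function(e) NULL)
    if (!is.null(AIinv)) {
      ses <- sqrt(pmax(diag(AIinv), 0))
      se_all <- numeric(k + ng)
      se_all[interior] <- ses
      se_u <- se_all[seq_len(k)]
      se_r <- se_all[k + seq_len(ng)]
    }
  }

  mme <- .solve_mme(y, X, Z, gidx, theta_u, theta_r)
  list(
    theta_u = theta_u, theta_r = theta_r, se_u = se_u, se_r = se_r,
    mu_hat = mme$mu_hat, blups = mme$blups, loglik = ll,
    converged = converged, n_iter = iter
  )
}

# Henderson's mixed-model equations at the REML estimates.
# Terms with zero variance contribute BLUP 0 / PEV 0.
.solve_mme <- function(y, X, Z, gidx, theta_u, theta_r) {
  n <- length(y)
  k <- length(Z)
  rvar <- numeric(n)
  for (g in seq_along(gidx)) rvar[gidx[[g]]] <- theta_r[g]
  rvar <- pmax(rvar, 1e-12 * (stats::var(y) + 1e-300))
  rinv <- 1 / rvar
  act <- which(theta_u > 0)
  W <- do.call(cbind, c(list(X), Z[act]))
  C <- crossprod(W * rinv, W)
  p <- ncol(X)
  pos <- p
  for (i in act) {
    qi <- ncol(Z[[i]])
    idx <- pos + seq_len(qi)
    diag(C)[idx] <- diag(C)[idx] + 1 / theta_u[i]
    pos <- pos + qi
  }
  Cinv <- solve(C)
  sol <- unname(drop(Cinv %*% crossprod(W * rinv, y)))
  pev <- unname(diag(Cinv))
  blups <- vector("list", k)
  names(blups) <- names(Z)
  pos <- p
  for (i in seq_len(k)) {
    lev <- colnames(Z[[i]])
    if (i %in% act) {
      idx <- pos + seq_along(lev)
      blups[[i]] <- tibble::tibble(level = lev, blup = sol[idx],
                                   pev = pev[idx])
      pos <- pos + length(lev)
    } else {
      blups[[i]] <- tibble::tibble(level = lev, blup = 0, pev = 0)
    }
  }
  list(mu_hat = sol[1], blups = blups)
}

#' @export
print.ncii_fit <- function(x, ...) {
  cat("Design II REML fit (", x$model, "), trait ", x$trait,
      ", n = ", x$n, "\n", sep = "")
  cat("  mu_hat = ", format(x$mu_hat, digits = 6),
      ";  REML logLik = ", format(x$reml_loglik, digits = 8),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  comp <- rbind(
    data.frame(term = x$components$term, estimate = x$components$estimate,
               se = x$components$se),
    data.frame(term = paste0("residual(", x$residual$group, ")"),
               estimate = x$residual$estimate, se = x$residual$se)
  )
  print(comp, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Design II REML fit
#'
#' One row per variance component (random terms, then residual groups as
#' `residual` / `residual:<year>`), with AI-based standard errors.
#'
#' @param x An `ncii_fit`.
#' @param ... Unused.
#' @method tidy ncii_fit
#' @export
tidy.ncii_fit <- function(x, ...) {
  res <- x$residual
  res_term <- if (nrow(res) == 1 && res$group[1] == "all") "residual" else
    paste0("residual:", res$group)
  dplyr::bind_rows(
    x$components,
    tibble::tibble(term = res_term, estimate = res$estimate, se = res$se)
  )
}

#' Glance at a Design II REML fit
#'
#' @param x An `ncii_fit`.
#' @param ... Unused.
#' @method glance ncii_fit
#' @export
glance.ncii_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, trait = x$trait, n = x$n, mu_hat = x$mu_hat,
    reml_loglik = x$reml_loglik, converged = x$converged,
    n_iter = x$n_iter
  )
}

#' Likelihood-ratio test for one variance component
#'
#' Compares a full fit with a reduced fit lacking exactly one random term,
#' using the boundary null distribution: an equal mixture of a point mass
#' at zero and a one-degree-of-freedom chi-square.
#'
#' @param full,reduced `ncii_fit` objects on the same data; `reduced` must
#'   omit exactly one of `full`'s random terms.
#' @return A one-row tibble: `term`, `statistic`, `p`, `stars`.
#' @export
lrt_variance <- function(full, reduced) {
  stopifnot(inherits(full, "ncii_fit"), inherits(reduced, "ncii_fit"))
  dropped <- setdiff(full$spec$terms, reduced$spec$terms)
  extra <- setdiff(reduced$spec$terms, full$spec$terms)
  if (length(extra) || length(dropped) != 1) {
    stop("reduced model must nest the full model by removing exactly one ",
         "random term", call. = FALSE)
  }
  if (full$n != reduced$n || full$trait != reduced$trait ||
      full$spec$residual != reduced$spec$residual) {
    stop("fits must use the same data and residual structure", call. = FALSE)
  }
  stat <- max(0, 2 * (full$reml_loglik - reduced$reml_loglik))
  p <- if (stat <= 0) 1 else
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  tibble::tibble(
    term = dropped, statistic = stat, p = p, stars = p_stars(p, ns = "ns")
  )
}

#' Adjusted means from a fitted model
#'
#' Level means of a genotype-like random term as intercept + BLUP.
#'
#' @param fit An `ncii_fit`.
#' @param term A random-term label of the fit (default `"genotype"`).
#' @return A tibble `level`, `blup`, `adjusted_mean`.
#' @export
adjusted_means <- function(fit, term = "genotype") {
  stopifnot(inherits(fit, "ncii_fit"))
  if (!term %in% names(fit$blups)) {
    stop("term '", term, "' has no BLUPs in this fit", call. = FALSE)
  }
  b <- fit$blups[[term]]
  tibble::tibble(
    level = b$level, blup = b$blup, adjusted_mean = fit$mu_hat + b$blup
  )
}

#' Two-tailed significance test for a BLUP
#'
#' `t = blup / sqrt(pev)` against the standard normal reference (residual
#' degrees of freedom in these designs run into the hundreds), with the
#' usual star annotation.
#'
#' @param blup Numeric vector of BLUP values.
#' @param pev Positive prediction-error variances, recycled against `blup`.
#' @return A tibble `blup`, `pev`, `t`, `p`, `stars`.
#' @export
blup_ttest <- function(blup, pev) {
  stopifnot(is.numeric(blup), is.numeric(pev))
  if (any(!is.finite(pev)) || any(pev <= 0)) {
    stop("pev must be positive", call. = FALSE)
  }
  t <- blup / sqrt(pev)
  p <- 2 * stats::pnorm(-abs(t))
  tibble::tibble(blup = blup, pev = pev, t = t, p = p,
                 stars = p_stars(p, ns = ""))
}
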