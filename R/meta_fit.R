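# Three-level random-effects meta-regression with a known sampling VCV.
#
# Model: y = X beta + Z_s u + e_obs + e_sampling, with
#   u ~ N(0, sigma2_study I_s), e_obs ~ N(0, sigma2_obs I_k),
#   e_sampling ~ N(0, V) with V the known delta-method VCV, so the marginal
#   covariance is Sigma(theta) = V + sigma2_study Z_s Z_s' + sigma2_obs I.
# Variance components are estimated by restricted maximum likelihood and the
# fixed effects by generalised least squares at the optimum.

# Restricted log-likelihood (with constants, matching the usual REML
# convention) profiled over beta. Returns -Inf for non-PD Sigma.
.reml_loglik <- function(theta, y, X, V, ZZt) {
  k <- length(y); p <- ncol(X)
  Sigma <- V + theta[1] * ZZt + theta[2] * diag(k)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetS <- 2 * sum(log(diag(ch)))
  # Sigma = U'U with U upper triangular; whitening by U'^-1 turns GLS into OLS
  W <- forwardsolve(t(ch), X)
  wy <- forwardsolve(t(ch), y)
  XtSiX <- crossprod(W)
  chB <- tryCatch(chol(XtSiX), error = function(e) NULL)
  if (is.null(chB)) return(-Inf)
  beta <- backsolve(chB, forwardsolve(t(chB), crossprod(W, wy)))
  rss <- sum((wy - W %*% beta)^2)
  logdetB <- 2 * sum(log(diag(chB)))
  -0.5 * ((k - p) * log(2 * pi) + logdetS + logdetB + rss)
}

# GLS solve at fixed theta; returns beta, vb, residuals, Sigma pieces.
.gls_at <- function(theta, y, X, V, ZZt) {
  k <- length(y)
  Sigma <- V + theta[1] * ZZt + theta[2] * diag(k)
  ch <- chol(Sigma)
  W <- forwardsolve(t(ch), X)
  wy <- forwardsolve(t(ch), y)
  XtSiX <- crossprod(W)
  vb <- chol2inv(chol(XtSiX))
  beta <- drop(vb %*% crossprod(W, wy))
  fitted <- unname(drop(X %*% beta))
  list(beta = beta, vb = vb, fitted = fitted, residuals = y - fitted,
       Sigma = Sigma, XtSiX = XtSiX)
}

#' Fit a multilevel random-effects meta-regression
#'
#' Fits the three-level meta-analytic model: effect sizes `y` with known
#' sampling covariance `V` (from [build_vcv()]), a study-level random
#' intercept with variance `sigma2_study`, and an observation-level random
#' intercept with variance `sigma2_obs`. Fixed effects are the moderators in
#' `moderators`; variance components are estimated by restricted maximum
#' likelihood (REML) over the marginal covariance
#' `Sigma = V + sigma2_study * Z_s Z_s' + sigma2_obs * I`, and coefficients by
#' generalised least squares at the optimum, so the inverse of the sampling
#' VCV (plus heterogeneity) weights effect precision.
#'
#' Optimisation uses bounded quasi-Newton (`nlminb`, lower bound 0 on both
#' components) from a multi-start grid over \{1e-4, 1e-2, 1e-1, 1\}^2, since
#' the restricted likelihood can be multimodal near zero components.
#' Continuous moderators are centred at their observed means by default
#' (affects only the intercept, not slopes or marginal means).
#'
#' @param effects An effect tibble ([build_effect_table()]).
#' @param vcv Optional sampling VCV aligned to `effects` (defaults to
#'   [build_vcv()] of the table; pass `diag(effects$variance)` to ignore
#'   covariances).
#' @param moderators One-sided formula of fixed-effect moderators over the
#'   effect table's columns, e.g. `~ condition + richness`. Default intercept
#'   only. Categorical terms use treatment coding with the alphabetically
#'   first level as reference.
#' @param center Centre continuous moderators at their observed means
#'   (default `TRUE`).
#' @param sigma2 Optional fixed variance components `c(study, obs)`; if
#'   supplied, REML estimation is skipped (used for closed-form checks and
#'   held-fixed refits).
#' @return An object of class `meta_fit`: a list with elements `beta` (named
#'   coefficients), `vb` (coefficient covariance), `sigma2` (named
#'   `c(study, obs)`), `logLik_reml`, `fitted`, `residuals`, `X`, `y`, `V`,
#'   `Sigma`, `data` (the effect tibble), `moderators`, `xlevels`, and
#'   `centers`. Supports [tidy()], [glance()], `print()`, and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' cells <- generate_dataset(synthetic_config(n_studies = 6, seed = 42))
#' nbe <- build_effect_table(cells, "nbe")
#' fit <- fit_meta(nbe, moderators = ~ condition + richness)
#' tidy(fit)
fit_meta <- function(effects, vcv = NULL, moderators = ~ 1, center = TRUE,
                     sigma2 = NULL) {
  if (is.null(vcv)) vcv <- build_vcv(effects)
  k <- nrow(effects)
  V <- unclass(vcv)
  if (!is.matrix(V) || nrow(V) != k || ncol(V) != k) {
    stop("vcv must be a ", k, "x", k, " matrix aligned to the effects",
         call. = FALSE)
  }
  y <- effects$value
  dm <- .design_matrix(effects, moderators, center = center)
  X <- dm$X
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("model error: design matrix is rank deficient (collinear terms: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(sigma2) && k < p + 2) {
    stop("model error: need at least p + 2 = ", p + 2, " effects, got ", k,
         call. = FALSE)
  }
  Zs <- stats::model.matrix(~ 0 + factor(effects$study_id))
  ZZt <- tcrossprod(Zs)

  if (is.null(sigma2)) {
    starts <- as.matrix(expand.grid(s = c(1e-4, 1e-2, 1e-1, 1),
                                    o = c(1e-4, 1e-2, 1e-1, 1)))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      op <- stats::nlminb(
        start = starts[i, ],
        objective = function(th) -.reml_loglik(th, y, X, V, ZZt),
        lower = c(0, 0),
        control = list(rel.tol = 1e-12, abs.tol = 1e-12, iter.max = 500)
      )
      if (is.null(best) || op$objective < best$objective - 1e-10) best <- op
    }
    sigma2 <- pmax(best$par, 0)
  } else {
    stopifnot(length(sigma2) == 2, all(sigma2 >= 0))
  }
  gls <- .gls_at(sigma2, y, X, V, ZZt)
  dimnames(gls$vb) <- list(colnames(X), colnames(X))
  structure(list(
    beta = stats::setNames(gls$beta, colnames(X)),
    vb = gls$vb,
    sigma2 = stats::setNames(sigma2, c("study", "obs")),
    logLik_reml = .reml_loglik(sigma2, y, X, V, ZZt),
    fitted = gls$fitted,
    residuals = gls$residuals,
    X = X, y = y, V = V, Sigma = gls$Sigma, XtSiX = gls$XtSiX,
    data = effects, moderators = moderators,
    xlevels = dm$xlevels, centers = dm$centers,
    k = k, p = p
  ), class = "meta_fit")
}

# Build the fixed-effect design matrix with treatment coding
# (alphabetically-first reference level) and optional centring of continuous
# moderators. Records levels and centres so prediction rows can be built.
.design_matrix <- function(effects, moderators, center = TRUE,
                           xlevels = NULL, centers = NULL) {
  mf_data <- as.data.frame(effects)
  vars <- all.vars(moderators)
  for (v in vars) {
    if (is.character(mf_data[[v]])) {
      lv <- if (!is.null(xlevels) && v %in% names(xlevels)) xlevels[[v]]
            else sort(unique(mf_data[[v]]))
      mf_data[[v]] <- factor(mf_data[[v]], levels = lv)
    }
  }
  found_levels <- lapply(
    mf_data[vars[vapply(mf_data[vars], is.factor, logical(1))]], levels)
  if (is.null(centers)) {
    centers <- vapply(
      vars[vapply(mf_data[vars], is.numeric, logical(1))],
      function(v) if (center) mean(mf_data[[v]]) else 0, numeric(1))
  }
  for (v in names(centers)) mf_data[[v]] <- mf_data[[v]] - centers[[v]]
  X <- stats::model.matrix(moderators, mf_data)
  list(X = X, xlevels = found_levels, centers = centers)
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("Multilevel meta-regression (REML)\n")
  cat(sprintf("  k = %d effects, p = %d coefficients\n", x$k, x$p))
  cat(sprintf("  sigma2_study = %.6g, sigma2_obs = %.6g\n",
              x$sigma2["study"], x$sigma2["obs"]))
  cat(sprintf("  restricted logLik = %.4f\n", x$logLik_reml))
  cat("Coefficients:\n")
  print(tidy(x), n = length(x$beta))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted meta-regression
#'
#' @param x A `meta_fit` object.
#' @param conf.level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per fixed coefficient: `term`, `estimate`,
#'   `std.error`, `statistic` (Wald z), `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.meta_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vb))
  z <- x$beta / se
  crit <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z))),
    conf.low = unname(x$beta - crit * se),
    conf.high = unname(x$beta + crit * se)
  )
}

#' One-row summary of a fitted meta-regression
#'
#' @param x A `meta_fit` object.
#' @param ... Unused.
#' @return A tibble with `k`, `p`, `sigma2.study`, `sigma2.obs`,
#'   `logLik.reml`.
#' @export
glance.meta_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, p = x$p,
    sigma2.study = unname(x$sigma2["study"]),
    sigma2.obs = unname(x$sigma2["obs"]),
    logLik.reml = x$logLik_reml
  )
}
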