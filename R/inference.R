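#' Omnibus moderator test (Q_M)
#'
#' Wald chi-square test that a subset of fixed coefficients is jointly zero:
#' `Q_M = b' Cov(b)^-1 b` on the selected coefficients, referred to a
#' chi-square distribution with df equal to the subset size.
#'
#' @param fit A `meta_fit` object.
#' @param terms Character vector of coefficient names (as in
#'   `names(fit$beta)`). Default: all non-intercept coefficients.
#' @return A one-row tibble: `QM`, `df`, `p.value`.
#' @export
#' @examples
#' cells <- generate_dataset(synthetic_config(n_studies = 6, seed = 7))
#' fit <- fit_meta(build_effect_table(cells, "nbe"),
#'                 moderators = ~ condition)
#' qm_test(fit, "conditionmanipulated")
qm_test <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "meta_fit"))
  if (is.null(terms)) terms <- setdiff(names(fit$beta), "(Intercept)")
  if (length(terms) == 0) stop("empty coefficient subset", call. = FALSE)
  unknown <- setdiff(terms, names(fit$beta))
  if (length(unknown) > 0) {
    stop("unknown coefficient(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(terms, names(fit$beta))
  b <- fit$beta[idx]
  Vb <- fit$vb[idx, idx, drop = FALSE]
  QM <- drop(crossprod(b, solve(Vb, b)))
  df <- length(idx)
  tibble::tibble(QM = QM, df = df,
                 p.value = stats::pchisq(QM, df, lower.tail = FALSE))
}

# Average design row for one level of `factor`: the fit's own effect rows with
# the factor forced to that level, continuous covariates at their observed
# means (the stored centres), other categorical moderators at their observed
# distribution.
.level_row <- function(fit, factor, level) {
  data <- fit$data
  data[[factor]] <- level
  X <- .design_matrix(data, fit$moderators, xlevels = fit$xlevels,
                      centers = fit$centers)$X
  colMeans(X)
}

#' Covariate-adjusted marginal means with Bonferroni-corrected intervals
#'
#' For each level of a categorical moderator, the model prediction at that
#' level with continuous covariates fixed at their observed means (and any
#' other categorical moderators averaged over their observed distribution),
#' with a Wald interval at level `1 - alpha/k` — the Bonferroni correction
#' over the family of `k` reported means (default: the number of levels).
#' A mean is flagged significant when its corrected interval excludes zero.
#'
#' @param fit A `meta_fit` object.
#' @param factor Name of a categorical moderator in the fit.
#' @param k Bonferroni family size; default the number of levels summarised.
#' @param alpha Nominal family-wise error rate (default 0.05).
#' @return A tibble: `level`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `k`, `significant`.
#' @export
marginal_means <- function(fit, factor, k = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "meta_fit"))
  if (!factor %in% names(fit$xlevels)) {
    stop("'", factor, "' is not a categorical moderator of this fit",
         call. = FALSE)
  }
  levels <- fit$xlevels[[factor]]
  if (is.null(k)) k <- length(levels)
  crit <- stats::qnorm(1 - alpha / (2 * k))
  rows <- purrr::map(levels, function(lv) {
    xb <- .level_row(fit, factor, lv)
    est <- drop(crossprod(xb, fit$beta))
    se <- sqrt(drop(crossprod(xb, fit$vb %*% xb)))
    tibble::tibble(level = lv, estimate = est, std.error = se,
                   conf.low = est - crit * se, conf.high = est + crit * se,
                   k = k)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(significant = .data$conf.low > 0 | .data$conf.high < 0)
}

#' Pairwise Wald contrasts among the levels of a moderator
#'
#' All pairwise differences of covariate-adjusted marginal means, tested with
#' Wald z statistics and Bonferroni-corrected p values over the number of
#' pairs.
#'
#' @param fit A `meta_fit` object.
#' @param factor Name of a categorical moderator with at least two levels.
#' @return A tibble: `pair`, `estimate`, `std.error`, `statistic`, `p.value`
#'   (uncorrected), `p.adjusted` (Bonferroni over the pairs).
#' @export
pairwise_contrasts <- function(fit, factor) {
  stopifnot(inherits(fit, "meta_fit"))
  if (!factor %in% names(fit$xlevels)) {
    stop("'", factor, "' is not a categorical moderator of this fit",
         call. = FALSE)
  }
  levels <- fit$xlevels[[factor]]
  if (length(levels) < 2) {
    stop("need at least 2 levels for pairwise contrasts", call. = FALSE)
  }
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    d <- .level_row(fit, factor, pr[2]) - .level_row(fit, factor, pr[1])
    est <- drop(crossprod(d, fit$beta))
    se <- sqrt(drop(crossprod(d, fit$vb %*% d)))
    z <- if (se > 0) est / se else 0
    tibble::tibble(pair = paste(pr[2], "-", pr[1]), estimate = est,
                   std.error = se, statistic = z,
                   p.value = 2 * stats::pnorm(-abs(z)))
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(p.adjusted = pmin(1, .data$p.value * length(pairs)))
}

#' Slope of a continuous moderator in the multilevel model
#'
#' Fits the meta-regression with the named continuous moderator alongside the
#' standard covariate set and returns its slope, standard error, and the
#' single-coefficient Q_M test.
#'
#' @param effects An effect tibble.
#' @param vcv Sampling VCV aligned to the effects (default [build_vcv()]).
#' @param moderator Name of a continuous column of the effect table.
#' @param covariates One-sided formula of additional covariates (default the
#'   standard set `~ richness + duration_years + unit_size_m2`, minus the
#'   moderator itself and any constant column).
#' @return A one-row tibble: `moderator`, `slope`, `std.error`, `QM`, `df`,
#'   `p.value`, plus the fit in the `fit` attribute.
#' @export
meta_regress_slope <- function(effects, vcv = NULL, moderator,
                               covariates = ~ richness + duration_years +
                                 unit_size_m2) {
  x <- effects[[moderator]]
  if (is.null(x)) stop("unknown moderator: ", moderator, call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("constant moderator: ", moderator, call. = FALSE)
  }
  covs <- setdiff(all.vars(covariates), moderator)
  covs <- covs[vapply(covs, function(v)
    length(unique(effects[[v]])) > 1, logical(1))]
  rhs <- paste(c(moderator, covs), collapse = " + ")
  fit <- fit_meta(effects, vcv = vcv,
                  moderators = stats::as.formula(paste("~", rhs)))
  qm <- qm_test(fit, moderator)
  out <- tibble::tibble(
    moderator = moderator,
    slope = unname(fit$beta[moderator]),
    std.error = sqrt(fit$vb[moderator, moderator]),
    QM = qm$QM, df = qm$df, p.value = qm$p.value
  )
  attr(out, "fit") <- fit
  out
}
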