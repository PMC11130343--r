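#' Funnel-plot data: residuals against sampling standard errors
#'
#' Pairs each effect's meta-regression residual (`y - X beta_hat`) with its
#' sampling standard error, the quantities inspected for funnel asymmetry.
#'
#' @param fit A `meta_fit` object.
#' @return A tibble with one row per effect: `effect_id`, `residual`,
#'   `std.error` (sampling SE, `sqrt(diag(V))`).
#' @export
funnel_data <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  tibble::tibble(
    effect_id = fit$data$effect_id,
    residual = fit$residuals,
    std.error = sqrt(diag(fit$V))
  )
}

#' Egger's regression test for funnel asymmetry
#'
#' Refits the multilevel meta-regression with each effect's sampling standard
#' error appended as an additional moderator; a significant SE coefficient
#' indicates funnel asymmetry consistent with small-study (publication) bias.
#'
#' @param effects An effect tibble.
#' @param vcv Sampling VCV (default [build_vcv()]).
#' @param moderators Moderator formula for the base model (default intercept
#'   only; pass the full analysis formula to run the test on the complete
#'   moderator model).
#' @return A one-row tibble: `estimate` (SE-moderator slope), `std.error`,
#'   `statistic` (Wald z), `p.value`, `significant` (at 0.05).
#' @export
egger_test <- function(effects, vcv = NULL, moderators = ~ 1) {
  if (nrow(effects) < 3) {
    stop("need at least 3 effects for Egger's regression", call. = FALSE)
  }
  if (is.null(vcv)) vcv <- build_vcv(effects)
  ses <- sqrt(diag(unclass(vcv)))
  if (diff(range(ses)) < .Machine$double.eps^0.5 * max(ses)) {
    stop("constant sampling standard errors: asymmetry not testable",
         call. = FALSE)
  }
  aug <- dplyr::mutate(effects, sampling_se = ses)
  rhs <- paste(c(attr(stats::terms(moderators), "term.labels"),
                 "sampling_se"), collapse = " + ")
  fit <- fit_meta(aug, vcv = vcv,
                  moderators = stats::as.formula(paste("~", rhs)))
  est <- unname(fit$beta["sampling_se"])
  se <- sqrt(fit$vb["sampling_se", "sampling_se"])
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(estimate = est, std.error = se, statistic = z,
                 p.value = p, significant = p < 0.05)
}

#' Cook's distances by leave-one-out refitting
#'
#' For each effect `i`, refits the model without it (variance components
#' re-estimated, VCV row/column dropped) and measures the coefficient shift
#' `D_i = (b - b_{-i})' (X' Sigma^-1 X) (b - b_{-i})`, scaled by the full-fit
#' precision. Effects with `D_i > threshold` (default the conventional
#' screening rule `4/k`) are flagged as influential. A refit failure for one
#' case is recorded as `NA`, not fatal.
#'
#' @param effects An effect tibble with `k > p + 2` rows.
#' @param vcv Sampling VCV (default [build_vcv()]).
#' @param moderators Moderator formula (default intercept only).
#' @param threshold Flagging threshold (default `4/k`).
#' @return A tibble: `effect_id`, `cooks_d`, `flagged`.
#' @export
cooks_distance_meta <- function(effects, vcv = NULL, moderators = ~ 1,
                                threshold = NULL) {
  if (is.null(vcv)) vcv <- build_vcv(effects)
  V <- unclass(vcv)
  k <- nrow(effects)
  full <- fit_meta(effects, vcv = V, moderators = moderators)
  if (k <= full$p + 2) {
    stop("need more than p + 2 effects for leave-one-out diagnostics",
         call. = FALSE)
  }
  if (is.null(threshold)) threshold <- 4 / k
  d <- vapply(seq_len(k), function(i) {
    sub <- effects[-i, , drop = FALSE]
    fit_i <- tryCatch(
      fit_meta(sub, vcv = V[-i, -i, drop = FALSE],
               moderators = moderators),
      error = function(e) NULL
    )
    if (is.null(fit_i) || length(fit_i$beta) != length(full$beta)) {
      return(NA_real_)
    }
    db <- full$beta - fit_i$beta
    drop(crossprod(db, full$XtSiX %*% db))
  }, numeric(1))
  tibble::tibble(
    effect_id = effects$effect_id,
    cooks_d = d,
    flagged = !is.na(d) & d > threshold
  )
}

#' Refit after removing flagged effects
#'
#' Sensitivity analysis: drops the flagged effects (and the matching rows and
#' columns of the sampling VCV) and refits the model on the remainder.
#'
#' @param effects An effect tibble.
#' @param vcv Sampling VCV (default [build_vcv()]).
#' @param moderators Moderator formula.
#' @param flagged Character vector of `effect_id`s to remove (e.g. from
#'   [cooks_distance_meta()]). An empty vector reproduces the full fit.
#' @return A `meta_fit` on the reduced effect set.
#' @export
sensitivity_refit <- function(effects, vcv = NULL, moderators = ~ 1,
                              flagged = character()) {
  if (is.null(vcv)) vcv <- build_vcv(effects)
  V <- unclass(vcv)
  unknown <- setdiff(flagged, effects$effect_id)
  if (length(unknown) > 0) {
    stop("flagged ids not in the effect table: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  keep <- !(effects$effect_id %in% flagged)
  if (sum(keep) == 0) stop("all effects flagged; nothing to refit",
                           call. = FALSE)
  fit_meta(effects[keep, , drop = FALSE],
           vcv = V[keep, keep, drop = FALSE], moderators = moderators)
}
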