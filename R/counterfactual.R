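#' Deseasonalised trajectory of a fitted ITS model
#'
#' The fitted trajectory with every seasonal and shock contribution set to its
#' reference level (zero) while trend and exposure contributions are retained:
#' `exp(intercept + trend + exposure)` per period.
#'
#' @param fit a converged `"its_fit"`.
#' @return Positive numeric vector, one value per period.
#' @export
deseasonalise <- function(fit) {
  predict(fit, type = "deseasonalised")
}

#' Counterfactual trajectory over the exposure window
#'
#' The no-pandemic trajectory restricted to the exposed periods: the exposure
#' contribution is set to zero. Two variants exist. The `"deseasonalised"`
#' variant (default) additionally removes seasonal and shock contributions and
#' is the dashed line drawn in trajectory plots. The `"seasonal"` variant
#' retains seasonality and is the one summed into counterfactual *totals*,
#' which must live on the observed count scale of real calendar periods.
#'
#' @param fit a converged `"its_fit"`.
#' @param type `"deseasonalised"` or `"seasonal"`.
#' @return Positive numeric vector over the exposed periods (named by period
#'   when the fit carries period labels).
#' @export
counterfactual_path <- function(fit, type = c("deseasonalised", "seasonal")) {
  type <- match.arg(type)
  check_converged(fit)
  exposed <- exposure_flag_from_fit(fit)
  if (!any(exposed)) stop("exposure window is empty", call. = FALSE)
  tt <- term_types(fit)
  drop <- c("exposure", if (type == "deseasonalised") c("season", "shock"))
  X <- fit$design
  X[, tt %in% drop] <- 0
  path <- as.numeric(exp(X %*% fit$coefficients))[exposed]
  if (!is.null(fit$periods)) names(path) <- fit$periods[exposed]
  path
}

#' Counterfactual total births over the exposure window, with standard error
#'
#' Point estimate: the sum over exposed periods of `exp(x_t' beta)` with the
#' exposure column of `x_t` zeroed and seasonal/shock columns retained - the
#' expected number of births in those calendar periods had pre-pandemic
#' trends continued. Standard error by the delta method on the coefficient
#' covariance: with gradient `g = sum_t exp(x_t' beta) x_t`,
#' `se = sqrt(g' V g)`.
#'
#' @param fit a converged `"its_fit"`.
#' @return A list with `total` (positive) and `se` (nonnegative).
#' @seealso [counterfactual_summary()], [relative_difference()]
#' @export
counterfactual_total <- function(fit) {
  check_converged(fit)
  exposed <- exposure_flag_from_fit(fit)
  tt <- term_types(fit)
  X <- fit$design
  X[, tt == "exposure"] <- 0
  Xe <- X[exposed, , drop = FALSE]
  mu <- as.numeric(exp(Xe %*% fit$coefficients))
  total <- sum(mu)
  g <- as.numeric(crossprod(Xe, mu))
  v <- as.numeric(g %*% fit$vcov %*% g)
  if (!is.finite(v) || v < -1e-8) {
    stop("non-finite delta-method variance (singular covariance?)",
         call. = FALSE)
  }
  list(total = total, se = sqrt(max(v, 0)))
}

#' Observed and counterfactual totals for one fitted group
#'
#' @param fit a converged `"its_poisson"` fit (must carry its group label).
#' @return One-row data frame: `group`, `observed_total`,
#'   `counterfactual_total`, `counterfactual_se`.
#' @export
counterfactual_summary <- function(fit) {
  check_converged(fit)
  ct <- counterfactual_total(fit)
  exposed <- exposure_flag_from_fit(fit)
  data.frame(
    group = if (is.null(fit$group)) NA_character_ else fit$group,
    observed_total = sum(fit$y[exposed]),
    counterfactual_total = ct$total,
    counterfactual_se = ct$se,
    stringsAsFactors = FALSE
  )
}

#' Relative difference between observed and counterfactual births
#'
#' `100 * (observed - counterfactual) / counterfactual` for one group, with a
#' Monte-Carlo percentile confidence interval computed from the same normal
#' draws of the counterfactual total used for the composition CIs: the
#' 2.5th/97.5th percentiles of `100 * (observed / draw - 1)`.
#'
#' @param summary a one-row data frame as from [counterfactual_summary()].
#' @param draws numeric vector of Monte-Carlo draws of this group's
#'   counterfactual total (e.g. one column of the draws stored by
#'   [mc_composition_ci()]). With `NULL`, only the point estimate is
#'   returned.
#' @return One-row data frame: `group`, `rel_diff_pct`, `ci_lo_pct`,
#'   `ci_hi_pct`.
#' @examples
#' s <- data.frame(group = "A", observed_total = 107,
#'                 counterfactual_total = 100, counterfactual_se = 0)
#' relative_difference(s)$rel_diff_pct  # 7
#' @export
relative_difference <- function(summary, draws = NULL) {
  stopifnot(is.data.frame(summary), nrow(summary) == 1L,
            summary$counterfactual_total > 0)
  pct <- 100 * (summary$observed_total - summary$counterfactual_total) /
    summary$counterfactual_total
  if (is.null(draws)) {
    lo <- hi <- NA_real_
  } else {
    if (any(draws <= 0)) {
      stop("nonpositive counterfactual draw(s); rerun the Monte-Carlo step ",
           "with truncate_at_zero = TRUE", call. = FALSE)
    }
    r <- 100 * (summary$observed_total / draws - 1)
    qs <- stats::quantile(r, c(0.025, 0.975), names = FALSE, type = 7)
    lo <- qs[1L]
    hi <- qs[2L]
  }
  data.frame(group = summary$group, rel_diff_pct = pct, ci_lo_pct = lo,
             ci_hi_pct = hi, stringsAsFactors = FALSE)
}
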