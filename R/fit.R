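#' Fit a Poisson interrupted-time-series model to one group's counts
#'
#' Maximum-likelihood Poisson regression with log link and no offset, fitted
#' by iteratively reweighted least squares with step-halving (relative
#' deviance change below 1e-10 or at most 100 iterations). The coefficient
#' covariance is the inverse Fisher information at the optimum.
#'
#' [its_poisson()] is the user-facing interface: it builds the design matrix
#' from a series and a [model_spec()] and fits one group. [fit_poisson_its()]
#' is the low-level engine taking a raw count vector and design matrix.
#'
#' @param y nonnegative integer counts, one per period (total > 0).
#' @param design numeric design matrix from [build_design_matrix()] (or any
#'   full-column-rank matrix with named columns).
#' @return An object of class `"its_fit"` (and, via [its_poisson()],
#'   `"its_poisson"`): a list with `coefficients`, `vcov`, `fitted_means`,
#'   `log_likelihood`, `converged`, `n_iterations`, `y` and `design`.
#' @seealso [deseasonalise()], [counterfactual_total()], [predict.its_fit()]
#' @examples
#' X <- cbind(`(Intercept)` = rep(1, 10))
#' f <- fit_poisson_its(rep(8L, 10), X)
#' coef(f)  # log(8)
#' @export
fit_poisson_its <- function(y, design) {
  if (!is.matrix(design) || is.null(colnames(design))) {
    stop("'design' must be a matrix with named columns", call. = FALSE)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(design)) {
    stop("length(y) must equal nrow(design)", call. = FALSE)
  }
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(y) == 0) stop("all counts are zero; nothing to fit", call. = FALSE)
  if (qr(design)$rank < ncol(design)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  fit <- stats::glm.fit(design, y, family = stats::poisson(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100L))
  beta <- stats::setNames(fit$coefficients, colnames(design))
  mu <- as.numeric(exp(design %*% beta))
  # Fisher information for the canonical log link: X' diag(mu) X
  xw <- design * sqrt(fit$weights)
  V <- tryCatch(chol2inv(chol(crossprod(xw))), error = function(e) NULL)
  converged <- isTRUE(fit$converged) && !is.null(V) && all(is.finite(beta))
  if (is.null(V)) V <- matrix(NA_real_, ncol(design), ncol(design))
  dimnames(V) <- list(colnames(design), colnames(design))
  structure(
    list(coefficients = beta, vcov = V, fitted_means = mu,
         log_likelihood = sum(stats::dpois(y, mu, log = TRUE)),
         converged = converged, n_iterations = fit$iter,
         y = y, design = design),
    class = "its_fit"
  )
}

#' @rdname fit_poisson_its
#' @param series a [grouped_count_series()].
#' @param spec a [model_spec()]; defaults to the standard specification for
#'   the series' frequency (quadratic trend, seasonal fixed effects, default
#'   exposure window, no shocks).
#' @param group group label to fit (must be a column of the series).
#' @export
its_poisson <- function(series, spec = model_spec(series$frequency), group) {
  stopifnot(inherits(series, "grouped_count_series"))
  if (!group %in% series$groups) {
    stop("group '", group, "' not present in series", call. = FALSE)
  }
  X <- build_design_matrix(series, spec)
  fit <- fit_poisson_its(series$counts[, group], X)
  fit$group <- group
  fit$periods <- series$periods
  fit$frequency <- series$frequency
  fit$spec <- spec
  class(fit) <- c("its_poisson", "its_fit")
  fit
}

check_converged <- function(fit) {
  stopifnot(inherits(fit, "its_fit"))
  if (!isTRUE(fit$converged)) {
    stop("Poisson ITS fit did not converge; refusing to use its estimates",
         call. = FALSE)
  }
  invisible(fit)
}

term_types <- function(fit) {
  tt <- attr(fit$design, "term_type")
  if (is.null(tt)) {
    # raw design without classification: treat every column as structural
    tt <- stats::setNames(rep("trend", ncol(fit$design)),
                          colnames(fit$design))
    tt[colnames(fit$design) == "(Intercept)"] <- "intercept"
    tt[colnames(fit$design) == "exposure"] <- "exposure"
  }
  tt
}

#' @export
print.its_fit <- function(x, ...) {
  cat("Poisson interrupted-time-series fit")
  if (!is.null(x$group)) cat(sprintf(" - group '%s'", x$group))
  cat("\n")
  cat(sprintf("  %d periods, %d coefficients, logLik %.2f, %s in %d iterations\n",
              length(x$y), length(x$coefficients), x$log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  if ("exposure" %in% names(x$coefficients)) {
    b <- x$coefficients[["exposure"]]
    se <- sqrt(x$vcov["exposure", "exposure"])
    cat(sprintf("  exposure level change: %+.4f (x%.3f), se %.4f\n",
                b, exp(b), se))
  }
  invisible(x)
}

#' @export
summary.its_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(estimate = object$coefficients, se = se, z = z,
               `p` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, log_likelihood = object$log_likelihood,
              converged = object$converged, group = object$group)
  class(out) <- "summary.its_fit"
  out
}

#' @export
print.summary.its_fit <- function(x, ...) {
  if (!is.null(x$group)) cat(sprintf("Group '%s'\n", x$group))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("logLik %.2f (%s)\n", x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.its_fit <- function(object, ...) object$coefficients

#' @export
vcov.its_fit <- function(object, ...) object$vcov

#' @export
logLik.its_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            class = "logLik")
}

#' @export
fitted.its_fit <- function(object, ...) object$fitted_means

#' @export
residuals.its_fit <- function(object,
                              type = c("deviance", "pearson", "response"),
                              ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted_means
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu),
    deviance = {
      d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
      sign(y - mu) * sqrt(pmax(d, 0))
    }
  )
}

#' Predicted trajectories from an ITS Poisson fit
#'
#' @param object an `"its_fit"`.
#' @param type `"response"` (fitted means), `"link"` (linear predictor),
#'   `"deseasonalised"` (seasonal and shock contributions removed, exposure
#'   retained) or `"counterfactual"` (exposure additionally removed; the full
#'   series of the no-pandemic trajectory).
#' @param ... unused.
#' @return Numeric vector, one value per period.
#' @export
predict.its_fit <- function(object,
                            type = c("response", "link", "deseasonalised",
                                     "counterfactual"), ...) {
  type <- match.arg(type)
  check_converged(object)
  if (type == "link") {
    return(as.numeric(object$design %*% object$coefficients))
  }
  if (type == "response") return(object$fitted_means)
  tt <- term_types(object)
  drop <- c("season", "shock", if (type == "counterfactual") "exposure")
  X <- object$design
  X[, tt %in% drop] <- 0
  as.numeric(exp(X %*% object$coefficients))
}

#' @export
simulate.its_fit <- function(object, nsim = 1, seed = NULL, ...) {
  check_converged(object)
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted_means)
  out <- as.data.frame(replicate(nsim, stats::rpois(n, object$fitted_means),
                                 simplify = FALSE),
                       col.names = paste0("sim_", seq_len(nsim)))
  if (!is.null(object$periods)) rownames(out) <- object$periods
  out
}

#' Plot observed, fitted, deseasonalised and counterfactual trajectories
#'
#' Mirrors the standard ITS display: observed counts as points, the fitted
#' seasonal model as a grey line, the deseasonalised trend as a solid black
#' line, the deseasonalised counterfactual (exposure effect removed) as a
#' dashed line, and a vertical rule at the start of the exposure window.
#'
#' @param x an `"its_poisson"` fit.
#' @param main plot title (defaults to the group label).
#' @param ... passed to [graphics::plot()].
#' @export
plot.its_poisson <- function(x, main = x$group, ...) {
  check_converged(x)
  n <- length(x$y)
  idx <- seq_len(n)
  des <- deseasonalise(x)
  cf <- predict(x, type = "counterfactual")
  graphics::plot(idx, x$y, pch = 16, cex = 0.4, col = "steelblue",
                 xlab = "period", ylab = "live births", main = main,
                 xaxt = "n", ...)
  at <- pretty(idx)
  at <- at[at >= 1 & at <= n]
  graphics::axis(1, at = at, labels = x$periods[at], las = 2, cex.axis = 0.7)
  graphics::lines(idx, x$fitted_means, col = "grey60")
  graphics::lines(idx, des, col = "black", lwd = 1.5)
  exposed <- exposure_flag_from_fit(x)
  graphics::lines(idx[exposed], cf[exposed], col = "black", lty = 2,
                  lwd = 1.5)
  graphics::abline(v = min(idx[exposed]), col = "grey30")
  invisible(x)
}

exposure_flag_from_fit <- function(fit) {
  X <- fit$design
  tt <- term_types(fit)
  if (!"exposure" %in% tt) stop("fit has no exposure term", call. = FALSE)
  X[, names(tt)[tt == "exposure"][1L]] > 0
}
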