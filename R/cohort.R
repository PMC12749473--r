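#' Counterfactual composition analysis of a birth cohort
#'
#' The package's main estimator. For every socioeconomic group in a count
#' series it fits the interrupted-time-series Poisson model, derives the
#' observed and counterfactual total births over the exposure window with a
#' delta-method standard error, converts the totals into observed and
#' counterfactual cohort compositions, and attaches percentage-point
#' differences with three-step Monte-Carlo percentile confidence intervals
#' plus per-group relative differences (the "x% more births than expected"
#' scale).
#'
#' @param series a [grouped_count_series()].
#' @param spec a [model_spec()]; defaults to the standard specification for
#'   the series' frequency.
#' @param n_draws Monte-Carlo replicates for the CIs (default 10,000).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param truncate_at_zero clamp negative normal draws at zero (see
#'   [mc_composition_ci()]).
#' @return An object of class `"cohort_composition"`: a list with `fits`
#'   (named list of [its_poisson()] fits), `summaries` (per-group totals and
#'   SEs), `composition` (a `"composition_result"`), `relative` (per-group
#'   relative differences with CIs), `spec`, `n_draws`, `seed`.
#' @examples
#' sc <- demo_scenario("monthly")
#' series <- generate_group_series(sc)
#' fit <- cohort_composition(series, n_draws = 2000, seed = 7)
#' fit
#' @export
cohort_composition <- function(series, spec = model_spec(series$frequency),
                               n_draws = 10000L, seed = 1L,
                               truncate_at_zero = FALSE) {
  stopifnot(inherits(series, "grouped_count_series"))
  fits <- lapply(series$groups, function(g) its_poisson(series, spec, g))
  names(fits) <- series$groups
  for (g in series$groups) {
    if (!fits[[g]]$converged) {
      stop("fit for group '", g, "' did not converge", call. = FALSE)
    }
  }
  summaries <- do.call(rbind, lapply(fits, counterfactual_summary))
  rownames(summaries) <- NULL
  comp <- mc_composition_ci(summaries, n_draws = n_draws, seed = seed,
                            truncate_at_zero = truncate_at_zero)
  draws <- attr(comp, "draws")
  relative <- do.call(rbind, lapply(seq_len(nrow(summaries)), function(i) {
    relative_difference(summaries[i, , drop = FALSE],
                        draws = draws[, summaries$group[i]])
  }))
  rownames(relative) <- NULL
  structure(
    list(fits = fits, summaries = summaries, composition = comp,
         relative = relative, spec = spec, n_draws = as.integer(n_draws),
         seed = as.integer(seed)),
    class = "cohort_composition"
  )
}

#' @export
print.cohort_composition <- function(x, ...) {
  cat("Counterfactual birth-cohort composition analysis\n")
  cat(sprintf("  %d groups, exposure %s .. %s, %d Monte-Carlo draws\n\n",
              length(x$fits), x$spec$exposure$start, x$spec$exposure$end,
              x$n_draws))
  df <- data.frame(
    group = x$composition$group,
    observed = formatC(x$summaries$observed_total, format = "d",
                       big.mark = ","),
    counterfactual = formatC(round(x$summaries$counterfactual_total),
                             format = "d", big.mark = ","),
    delta_pp = sprintf("%+.2f [%+.2f; %+.2f]", x$composition$delta_pp,
                       x$composition$ci_lo_pp, x$composition$ci_hi_pp),
    rel_diff = sprintf("%+.1f%% [%+.1f%%; %+.1f%%]", x$relative$rel_diff_pct,
                       x$relative$ci_lo_pct, x$relative$ci_hi_pct)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cohort_composition <- function(object, ...) {
  out <- merge(object$summaries,
               as.data.frame(object$composition), by = "group", sort = FALSE)
  out <- merge(out, object$relative, by = "group", sort = FALSE)
  conv <- vapply(object$fits, `[[`, TRUE, "converged")
  out$converged <- conv[out$group]
  out
}

#' @export
coef.cohort_composition <- function(object, ...) {
  sapply(object$fits, coef)
}

#' Dot-and-interval plot of compositional differences
#'
#' One point per group at its percentage-point difference between observed
#' and counterfactual cohort composition, with horizontal 95% Monte-Carlo
#' confidence bars and a reference line at zero.
#'
#' @param x a `"cohort_composition"` or `"composition_result"`.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cohort_composition <- function(x, main = "Change in cohort composition",
                                    ...) {
  plot_composition(x$composition, main = main, ...)
}

#' @rdname plot.cohort_composition
#' @export
plot.composition_result <- function(x, main = "Change in cohort composition",
                                    ...) {
  plot_composition(x, main = main, ...)
}

plot_composition <- function(comp, main, ...) {
  k <- nrow(comp)
  ypos <- rev(seq_len(k))
  xlim <- range(0, comp$ci_lo_pp, comp$ci_hi_pp)
  graphics::plot(comp$delta_pp, ypos, pch = 16, xlim = xlim,
                 ylim = c(0.5, k + 0.5), yaxt = "n", ylab = "",
                 xlab = "percentage-point difference (observed - counterfactual)",
                 main = main, ...)
  graphics::axis(2, at = ypos, labels = comp$group, las = 1, cex.axis = 0.8)
  graphics::segments(comp$ci_lo_pp, ypos, comp$ci_hi_pp, ypos)
  graphics::abline(v = 0, lty = 3, col = "grey40")
  invisible(comp)
}
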