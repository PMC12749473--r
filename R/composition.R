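#' Compositional difference between observed and counterfactual cohorts
#'
#' Point estimates of the percentage-point change in each group's share of
#' the exposed birth cohort: observed proportions `p_g = observed_g / sum
#' observed`, counterfactual proportions `q_g = counterfactual_g / sum
#' counterfactual`, and `delta_pp = 100 * (p_g - q_g)`. Deltas always sum to
#' zero because both compositions normalise to one.
#'
#' @param summaries data frame with one row per group and columns `group`,
#'   `observed_total`, `counterfactual_total`, `counterfactual_se` (rows from
#'   [counterfactual_summary()], stacked).
#' @return Data frame with columns `group`, `observed_prop`,
#'   `counterfactual_prop`, `delta_pp`.
#' @examples
#' s <- data.frame(group = c("A", "B"), observed_total = c(55, 45),
#'                 counterfactual_total = c(50, 50),
#'                 counterfactual_se = c(0, 0))
#' composition_delta(s)$delta_pp  # +5, -5
#' @export
composition_delta <- function(summaries) {
  check_summaries(summaries)
  p <- summaries$observed_total / sum(summaries$observed_total)
  q <- summaries$counterfactual_total / sum(summaries$counterfactual_total)
  data.frame(group = summaries$group, observed_prop = p,
             counterfactual_prop = q, delta_pp = 100 * (p - q),
             stringsAsFactors = FALSE)
}

check_summaries <- function(summaries) {
  need <- c("group", "observed_total", "counterfactual_total",
            "counterfactual_se")
  if (!is.data.frame(summaries) || !all(need %in% names(summaries))) {
    stop("'summaries' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(summaries) < 2L) {
    stop("composition needs at least two groups", call. = FALSE)
  }
  if (any(summaries$counterfactual_total <= 0)) {
    stop("all counterfactual totals must be positive", call. = FALSE)
  }
  if (all(summaries$observed_total == 0)) {
    stop("observed totals are all zero", call. = FALSE)
  }
  if (any(summaries$counterfactual_se < 0)) {
    stop("negative standard error", call. = FALSE)
  }
  if (anyDuplicated(summaries$group)) {
    stop("duplicate group labels", call. = FALSE)
  }
  invisible(summaries)
}

#' Three-step Monte-Carlo confidence intervals for compositional differences
#'
#' The percentile CI procedure for the percentage-point differences. Per
#' replicate: (1) draw each group's counterfactual total independently from
#' `Normal(counterfactual_total_g, counterfactual_se_g)`; (2) renormalise the
#' draws into a counterfactual composition `q_g = X_g / sum_h X_h`; (3) take
#' the percentage-point difference against the *observed* composition,
#' `d_g = 100 * (p_g - q_g)`. After `n_draws` replicates the CI bounds are
#' the empirical 2.5th and 97.5th percentiles of each group's `d_g`
#' distribution (linear interpolation between order statistics, so bounds are
#' bit-reproducible given the seed).
#'
#' Draws use one random stream, filled replicate-by-replicate in alphabetical
#' group order, so results depend neither on parallelisation nor on the row
#' order of `summaries`. Negative draws are left
#' untruncated by default (standard errors are in practice far smaller than
#' the totals); `truncate_at_zero = TRUE` clamps them at zero for scenarios
#' with tiny counts. A replicate whose draws sum to a nonpositive value
#' cannot be renormalised and raises an error.
#'
#' @param summaries data frame as for [composition_delta()].
#' @param n_draws number of Monte-Carlo replicates (default 10,000; a warning
#'   is issued below 1,000).
#' @param seed integer seed for the draws.
#' @param truncate_at_zero clamp negative normal draws at zero.
#' @return An object of class `"composition_result"`: a data frame with
#'   columns `group`, `observed_prop`, `counterfactual_prop`, `delta_pp`,
#'   `ci_lo_pp`, `ci_hi_pp`, `n_draws`, `seed`, plus attributes `draws` (the
#'   n_draws x groups matrix of normal draws, reused by
#'   [relative_difference()]) and `truncate_at_zero`.
#' @export
mc_composition_ci <- function(summaries, n_draws = 10000L, seed = 1L,
                              truncate_at_zero = FALSE) {
  check_summaries(summaries)
  n_draws <- as.integer(n_draws)
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  if (n_draws < 1000L) {
    warning("fewer than 1,000 draws; confidence bounds will be noisy",
            call. = FALSE)
  }
  point <- composition_delta(summaries)
  G <- nrow(summaries)
  set.seed(as.integer(seed))
  # one stream, filled replicate-by-replicate in alphabetical group order, so
  # the draws attached to a group do not depend on input row order
  ord <- order(summaries$group)
  Xs <- matrix(stats::rnorm(n_draws * G,
                            mean = rep(summaries$counterfactual_total[ord],
                                       n_draws),
                            sd = rep(summaries$counterfactual_se[ord],
                                     n_draws)),
               nrow = n_draws, ncol = G, byrow = TRUE)
  X <- Xs[, match(seq_len(G), ord), drop = FALSE]
  colnames(X) <- summaries$group
  if (truncate_at_zero) X[X < 0] <- 0
  rs <- rowSums(X)
  if (any(rs <= 0)) {
    stop("replicate(s) with nonpositive total counterfactual draw; ",
         "cannot renormalise (first at replicate ", which(rs <= 0)[1L], ")",
         call. = FALSE)
  }
  Q <- X / rs
  D <- 100 * sweep(-Q, 2L, point$observed_prop, `+`)  # d_g = 100 (p_g - q_g)
  ci <- apply(D, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE,
              type = 7)
  out <- data.frame(point, ci_lo_pp = ci[1L, ], ci_hi_pp = ci[2L, ],
                    n_draws = n_draws, seed = as.integer(seed),
                    stringsAsFactors = FALSE)
  attr(out, "draws") <- X
  attr(out, "truncate_at_zero") <- truncate_at_zero
  class(out) <- c("composition_result", "data.frame")
  out
}

#' @export
print.composition_result <- function(x, digits = 3, ...) {
  cat(sprintf("Compositional differences, %d Monte-Carlo draws (seed %d)\n",
              x$n_draws[1L], x$seed[1L]))
  df <- data.frame(group = x$group,
                   observed = round(x$observed_prop, 4),
                   counterfactual = round(x$counterfactual_prop, 4),
                   delta_pp = round(x$delta_pp, digits),
                   ci = sprintf("[%+.*f; %+.*f]", digits, x$ci_lo_pp,
                                digits, x$ci_hi_pp))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Empirical coverage of the Monte-Carlo composition CIs
#'
#' Simulation experiment validating the three-step CI procedure against a
#' scenario's known ground truth: regenerate the register `n_replicates`
#' times, run the full fit-and-compose pipeline on each replicate, and count
#' how often each group's 95% CI contains the true percentage-point delta
#' from [true_counterfactual_summary()].
#'
#' @param scenario a [synthetic_scenario()].
#' @param n_replicates number of simulated registers (warn below 50).
#' @param n_draws Monte-Carlo draws per replicate CI.
#' @param seed integer seed governing both regeneration and the CI draws.
#' @return Data frame per group: `group`, `true_delta_pp`, `coverage`,
#'   `mc_se` (binomial Monte-Carlo error), `n_replicates`.
#' @export
coverage_experiment <- function(scenario, n_replicates = 200L,
                                n_draws = 2000L, seed = 1L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (n_replicates < 50L) {
    warning("fewer than 50 replicates; coverage estimate will be crude",
            call. = FALSE)
  }
  truth <- true_counterfactual_summary(scenario)
  spec <- model_spec(scenario$frequency, exposure = scenario$exposure,
                     shocks = scenario$shock_windows)
  hits <- matrix(FALSE, n_replicates, nrow(truth),
                 dimnames = list(NULL, truth$group))
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, 2L * n_replicates)
  for (r in seq_len(n_replicates)) {
    series <- generate_group_series(scenario, seed = rep_seeds[2L * r - 1L])
    summaries <- do.call(rbind, lapply(series$groups, function(g) {
      counterfactual_summary(its_poisson(series, spec, g))
    }))
    res <- mc_composition_ci(summaries, n_draws = n_draws,
                             seed = rep_seeds[2L * r])
    res <- res[match(truth$group, res$group), ]
    hits[r, ] <- truth$true_delta_pp >= res$ci_lo_pp &
      truth$true_delta_pp <= res$ci_hi_pp
  }
  cov <- colMeans(hits)
  data.frame(group = truth$group, true_delta_pp = truth$true_delta_pp,
             coverage = as.numeric(cov),
             mc_se = sqrt(cov * (1 - cov) / n_replicates),
             n_replicates = n_replicates,
             stringsAsFactors = FALSE, row.names = NULL)
}
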