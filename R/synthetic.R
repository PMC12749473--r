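#' Ground-truth parameters for one synthetic group
#'
#' Describes the generative log-linear model of one socioeconomic group's
#' count series: log expected count = `intercept` + `trend[1]` * t_lin +
#' `trend[2]` * t_lin^2 + seasonal effect + exposure effect (inside the
#' exposure window) + shock effects (inside their windows), where t_lin is the
#' same centred/scaled sequential index used by the fitting side, so truth and
#' estimates are directly comparable.
#'
#' @param name group label (a missing-information category is just another
#'   group).
#' @param intercept log expected count at the centre of the span, reference
#'   season, outside all windows.
#' @param trend numeric length 2: linear and quadratic coefficients on the
#'   centred/scaled index.
#' @param seasonal seasonal log-effects of length 12 (monthly) or 52/53
#'   (weekly); the first (reference) entry must be exactly 0. `NULL` means no
#'   seasonality. With length 52, ISO week 53 reuses the week-52 effect.
#' @param exposure_effect log level change over the exposure window
#'   (`ln(1.07)` is a 7\% increase).
#' @param shock_effects named numeric vector of log level changes, names
#'   matching the scenario's shock-window labels.
#' @return An object of class `"scenario_group"`.
#' @export
scenario_group <- function(name, intercept, trend = c(0, 0), seasonal = NULL,
                           exposure_effect = 0, shock_effects = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(intercept), length(intercept) == 1L,
            is.numeric(trend), length(trend) == 2L,
            is.numeric(exposure_effect), length(exposure_effect) == 1L)
  if (!is.null(seasonal)) {
    if (seasonal[1L] != 0) {
      stop("seasonal effect of the reference period must be exactly 0",
           call. = FALSE)
    }
  }
  if (!is.null(shock_effects) &&
      (is.null(names(shock_effects)) || any(!nzchar(names(shock_effects))))) {
    stop("shock_effects must be a named vector", call. = FALSE)
  }
  structure(list(name = name, intercept = intercept, trend = trend,
                 seasonal = seasonal, exposure_effect = exposure_effect,
                 shock_effects = shock_effects),
            class = "scenario_group")
}

#' Synthetic birth-register scenario with known ground truth
#'
#' Defines a multi-year weekly or monthly synthetic vital-registration
#' scenario: per-group secular trends (linear + quadratic), week/month-of-year
#' seasonality, optional transient shocks (a Zika-style dip), and a
#' group-specific level change over the pandemic-conception exposure window.
#' Counts are Poisson with the log-linear mean structure documented in
#' [scenario_group()], mirroring term-for-term the regression fitted
#' downstream, so every estimate has an exact generative counterpart.
#'
#' @param frequency `"weekly"` or `"monthly"`.
#' @param start,end period labels spanning the series (inclusive).
#' @param groups list of [scenario_group()] objects (at least one).
#' @param exposure an [exposure_window()]; default the frequency's standard
#'   window ([default_exposure_window()]).
#' @param shock_windows list of [shock_window()] objects.
#' @param seed default integer seed for generation (can be overridden at
#'   generation time).
#' @return An object of class `"synthetic_scenario"`.
#' @examples
#' sc <- synthetic_scenario("monthly", "2019-01", "2021-12",
#'   groups = list(scenario_group("A", log(100))))
#' range(exp(scenario_logmu(sc)))
#' @export
synthetic_scenario <- function(frequency, start, end, groups,
                               exposure = default_exposure_window(frequency),
                               shock_windows = list(), seed = 1L) {
  frequency <- match_frequency(frequency)
  if (!is.list(groups) || length(groups) == 0L) {
    stop("'groups' must be a non-empty list of scenario_group objects",
         call. = FALSE)
  }
  stopifnot(all(vapply(groups, inherits, TRUE, "scenario_group")))
  nm <- vapply(groups, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate group names", call. = FALSE)
  names(groups) <- nm
  periods <- period_seq(start, end, frequency)
  season_len <- if (frequency == "weekly") c(52L, 53L) else 12L
  shock_labels <- vapply(shock_windows, `[[`, "", "label")
  for (g in groups) {
    if (!is.null(g$seasonal) && !(length(g$seasonal) %in% season_len)) {
      stop("group '", g$name, "': seasonal effects must have length ",
           paste(season_len, collapse = " or "), call. = FALSE)
    }
    bad <- setdiff(names(g$shock_effects), shock_labels)
    if (length(bad)) {
      stop("group '", g$name, "' has shock effects without windows: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (any(vapply(groups, function(g) g$exposure_effect != 0, TRUE)) &&
      period_start(end, frequency) <
        period_start(exposure$start, frequency)) {
    stop("series ends before the exposure window but an exposure effect is nonzero",
         call. = FALSE)
  }
  sc <- structure(
    list(frequency = frequency, start = start, end = end, periods = periods,
         groups = groups, exposure = exposure,
         shock_windows = shock_windows, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
  lm <- scenario_logmu(sc)
  if (any(!is.finite(lm)) || any(lm > 700)) {
    bad <- which(!is.finite(lm) | lm > 700, arr.ind = TRUE)[1L, ]
    stop("non-finite expected count for group '", colnames(lm)[bad[2L]],
         "' at period ", rownames(lm)[bad[1L]], call. = FALSE)
  }
  sc
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("Synthetic %s birth-register scenario\n", x$frequency))
  cat(sprintf("  span: %s .. %s (%d periods)\n", x$start, x$end,
              length(x$periods)))
  cat(sprintf("  exposure: %s .. %s\n", x$exposure$start, x$exposure$end))
  for (g in x$groups) {
    cat(sprintf("  group %-14s mean level %8.1f  exposure x%.3f\n", g$name,
                exp(g$intercept), exp(g$exposure_effect)))
  }
  invisible(x)
}

#' Log expected counts implied by a scenario's ground truth
#'
#' @param scenario a [synthetic_scenario()].
#' @param exposure_on include the exposure effect (set `FALSE` for the
#'   counterfactual mean path).
#' @param shocks_on include shock effects.
#' @param season_on include seasonal effects.
#' @return Numeric matrix (periods x groups) of log means.
#' @export
scenario_logmu <- function(scenario, exposure_on = TRUE, shocks_on = TRUE,
                           season_on = TRUE) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  periods <- scenario$periods
  n <- length(periods)
  t0 <- seq_len(n) - 1L
  t_lin <- (t0 - mean(t0)) / n
  lev <- period_of_year(periods, scenario$frequency)
  eflag <- window_flag(periods, scenario$frequency,
                       scenario$exposure$start, scenario$exposure$end)
  out <- matrix(0, n, length(scenario$groups),
                dimnames = list(periods, names(scenario$groups)))
  for (g in scenario$groups) {
    lm <- g$intercept + g$trend[1L] * t_lin + g$trend[2L] * t_lin^2
    if (season_on && !is.null(g$seasonal)) {
      s <- g$seasonal
      if (scenario$frequency == "weekly" && length(s) == 52L) {
        s <- c(s, s[52L])  # week 53 reuses the week-52 effect
      }
      lm <- lm + s[lev]
    }
    if (shocks_on) {
      for (sh in scenario$shock_windows) {
        eff <- g$shock_effects[sh$label]
        if (!is.null(eff) && !is.na(eff) && eff != 0) {
          lm <- lm + eff * window_flag(periods, scenario$frequency,
                                       sh$start, sh$end)
        }
      }
    }
    if (exposure_on && g$exposure_effect != 0) {
      lm <- lm + g$exposure_effect * eflag
    }
    out[, g$name] <- lm
  }
  out
}

#' Generate a grouped count series from a synthetic scenario
#'
#' Draws `count ~ Poisson(mu)` independently for every (period, group) with
#' the log-linear means implied by the scenario truth. Reproducible: the same
#' seed always yields the same series.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed integer seed; defaults to the scenario's own seed.
#' @return A [grouped_count_series()] flagged with the scenario's exposure
#'   window.
#' @export
generate_group_series <- function(scenario, seed = scenario$seed) {
  mu <- exp(scenario_logmu(scenario))
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(length(mu), mu), nrow(mu),
                   dimnames = dimnames(mu))
  grouped_count_series(counts, scenario$frequency, scenario$exposure)
}

#' Generate individual-level synthetic birth records
#'
#' Draws the same per-(period, group) Poisson counts as
#' [generate_group_series()] (identical seed gives identical totals), then
#' assigns each record a birth date uniform over the days of its period.
#' Optional covariates give plausible register-like columns: maternal age
#' (normal, mean 30, sd 5, clamped to 15-49), parity (1 + Poisson(0.9)) and a
#' group-shifted continuous socioeconomic score.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed integer seed; defaults to the scenario's own seed.
#' @param covariates logical; add `maternal_age`, `parity` and
#'   `continuous_ses` columns.
#' @return A data frame with columns `date_of_birth` (Date) and `group` (and
#'   covariates when requested), ordered by period then group.
#' @export
generate_birth_records <- function(scenario, seed = scenario$seed,
                                   covariates = FALSE) {
  mu <- exp(scenario_logmu(scenario))
  freq <- scenario$frequency
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(length(mu), mu), nrow(mu),
                   dimnames = dimnames(mu))
  starts <- period_start(rownames(counts), freq)
  ndays <- if (freq == "weekly") {
    rep(7L, length(starts))
  } else {
    as.integer(c(diff(starts), diff(seq(starts[length(starts)],
                                        by = "month", length.out = 2L))))
  }
  total <- sum(counts)
  idx <- which(counts > 0, arr.ind = TRUE)
  per_i <- rep(idx[, 1L], counts[idx])
  grp_i <- rep(idx[, 2L], counts[idx])
  offs <- floor(stats::runif(total) * ndays[per_i])
  rec <- data.frame(
    date_of_birth = starts[per_i] + offs,
    group = colnames(counts)[grp_i],
    stringsAsFactors = FALSE
  )
  if (covariates) {
    age <- pmin(pmax(stats::rnorm(total, 30, 5), 15), 49)
    rec$maternal_age <- round(age, 1)
    rec$parity <- 1L + stats::rpois(total, 0.9)
    rec$continuous_ses <- stats::rnorm(total, mean = grp_i, sd = 1)
  }
  ord <- order(per_i, grp_i)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Ground-truth counterfactual summary of a scenario
#'
#' The closed-form quantities every downstream estimate targets: for each
#' group, the counterfactual total over the exposure window (expected counts
#' with the exposure effect switched off), the expected observed total (all
#' effects on), and the true compositional difference in percentage points,
#' computed from these expectations exactly as [composition_delta()] computes
#' it from estimates.
#'
#' @param scenario a [synthetic_scenario()].
#' @return A data frame with one row per group: `group`,
#'   `observed_expectation_total`, `counterfactual_total`, `observed_prop`,
#'   `counterfactual_prop`, `true_delta_pp`, `true_rel_diff_pct`.
#' @export
true_counterfactual_summary <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  eflag <- window_flag(scenario$periods, scenario$frequency,
                       scenario$exposure$start, scenario$exposure$end)
  if (!any(eflag)) {
    stop("scenario span does not contain the exposure window", call. = FALSE)
  }
  mu_obs <- exp(scenario_logmu(scenario, exposure_on = TRUE))
  mu_cf <- exp(scenario_logmu(scenario, exposure_on = FALSE))
  obs <- colSums(mu_obs[eflag, , drop = FALSE])
  cf <- colSums(mu_cf[eflag, , drop = FALSE])
  p <- obs / sum(obs)
  q <- cf / sum(cf)
  data.frame(
    group = names(scenario$groups),
    observed_expectation_total = as.numeric(obs),
    counterfactual_total = as.numeric(cf),
    observed_prop = as.numeric(p),
    counterfactual_prop = as.numeric(q),
    true_delta_pp = 100 * as.numeric(p - q),
    true_rel_diff_pct = 100 * as.numeric(obs / cf - 1),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Sinusoidal seasonal profile with zero reference effect
#'
#' A mild single-cycle seasonal pattern on the log scale (births peak in
#' late summer in most European registers); the first week/month is the
#' reference with effect exactly 0.
#'
#' @param frequency `"weekly"` or `"monthly"`.
#' @param amplitude peak log-effect (default 0.06, i.e. about +/- 6\%).
#' @param phase phase shift in cycles (default 0.6, placing the peak around
#'   late summer relative to a January reference).
#' @return Numeric vector of length 52 or 12 with first element 0.
#' @export
seasonal_profile <- function(frequency, amplitude = 0.06, phase = 0.6) {
  frequency <- match_frequency(frequency)
  k <- if (frequency == "weekly") 52L else 12L
  s <- amplitude * sin(2 * pi * ((seq_len(k) - 1L) / k + phase))
  s - s[1L]
}

#' Built-in demonstration scenarios
#'
#' Two ready-made scenarios used throughout the examples, tests and the
#' acceptance script.
#'
#' `demo_scenario("monthly")` emulates a small European country with
#' education-style groups (advantaged / middle / disadvantaged / missing)
#' at a combined level of roughly 7,100 births per month over 2015-01 to
#' 2021-12, mild seasonality, gently declining trends, and exposure
#' multipliers 1.05 / 1.01 / 0.97 / 1 over 2020-12 to 2021-12.
#'
#' `demo_scenario("weekly")` is a two-group weekly design over seven years
#' (2015-W01 to 2021-W51, exposure 2020-W51 onward, 54 weeks) with about 500
#' births per week in each group and exposure multipliers 1.07 (advantaged)
#' and 1 (disadvantaged).
#'
#' @param frequency `"weekly"` or `"monthly"`.
#' @param null logical; if `TRUE` all exposure effects are set to 0 (used for
#'   coverage experiments under the no-pandemic-effect null).
#' @param seed scenario seed.
#' @return A [synthetic_scenario()].
#' @export
demo_scenario <- function(frequency = c("weekly", "monthly"), null = FALSE,
                          seed = 1L) {
  frequency <- match.arg(frequency)
  if (frequency == "weekly") {
    seas <- seasonal_profile("weekly")
    eff <- if (null) c(0, 0) else c(log(1.07), 0)
    synthetic_scenario(
      "weekly", "2015-W01", "2021-W51",
      groups = list(
        scenario_group("advantaged", log(500), trend = c(0.05, -0.02),
                       seasonal = seas, exposure_effect = eff[1L]),
        scenario_group("disadvantaged", log(500), trend = c(-0.12, 0.03),
                       seasonal = seas, exposure_effect = eff[2L])
      ),
      exposure = default_exposure_window("weekly"),
      seed = seed
    )
  } else {
    seas <- seasonal_profile("monthly")
    eff <- if (null) c(0, 0, 0, 0) else c(log(1.05), log(1.01), log(0.97), 0)
    synthetic_scenario(
      "monthly", "2015-01", "2021-12",
      groups = list(
        scenario_group("advantaged", log(2100), trend = c(0.06, -0.02),
                       seasonal = seas, exposure_effect = eff[1L]),
        scenario_group("middle", log(3200), trend = c(-0.08, 0.02),
                       seasonal = seas, exposure_effect = eff[2L]),
        scenario_group("disadvantaged", log(1400), trend = c(-0.15, 0.04),
                       seasonal = seas, exposure_effect = eff[3L]),
        scenario_group("missing", log(350), trend = c(0, 0),
                       seasonal = seas, exposure_effect = eff[4L])
      ),
      exposure = default_exposure_window("monthly"),
      seed = seed
    )
  }
}

#' Read and write scenario files
#'
#' Scenarios are serialised as YAML, one document per scenario, so that the
#' pipeline can be driven entirely from configuration files.
#'
#' @param scenario a [synthetic_scenario()].
#' @param file path to a YAML file.
#' @return `read_scenario()` returns a [synthetic_scenario()];
#'   `write_scenario()` invisibly returns `file`.
#' @export
write_scenario <- function(scenario, file) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  doc <- list(
    frequency = scenario$frequency,
    start = scenario$start,
    end = scenario$end,
    seed = scenario$seed,
    exposure = list(start = scenario$exposure$start,
                    end = scenario$exposure$end),
    shock_windows = lapply(scenario$shock_windows, function(sh) {
      list(label = sh$label, start = sh$start, end = sh$end)
    }),
    groups = lapply(scenario$groups, function(g) {
      out <- list(name = g$name, intercept = g$intercept,
                  trend = as.numeric(g$trend),
                  exposure_effect = g$exposure_effect)
      if (!is.null(g$seasonal)) out$seasonal <- as.numeric(g$seasonal)
      if (!is.null(g$shock_effects)) {
        out$shock_effects <- as.list(g$shock_effects)
      }
      out
    })
  )
  yaml::write_yaml(doc, file, precision = 15L)
  invisible(file)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(file) {
  doc <- yaml::read_yaml(file)
  shocks <- lapply(doc$shock_windows, function(sh) {
    shock_window(sh$label, sh$start, sh$end)
  })
  groups <- lapply(doc$groups, function(g) {
    scenario_group(
      g$name, g$intercept,
      trend = if (is.null(g$trend)) c(0, 0) else as.numeric(g$trend),
      seasonal = if (is.null(g$seasonal)) NULL else as.numeric(g$seasonal),
      exposure_effect = if (is.null(g$exposure_effect)) 0 else
        g$exposure_effect,
      shock_effects = if (is.null(g$shock_effects)) NULL else
        unlist(g$shock_effects)
    )
  })
  synthetic_scenario(
    doc$frequency, doc$start, doc$end, groups,
    exposure = if (is.null(doc$exposure)) {
      default_exposure_window(doc$frequency)
    } else {
      exposure_window(doc$exposure$start, doc$exposure$end)
    },
    shock_windows = shocks,
    seed = if (is.null(doc$seed)) 1L else doc$seed
  )
}
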