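#' Exposure and shock windows
#'
#' An exposure window marks the birth cohort potentially conceived during the
#' pandemic. The defaults follow the convention that roughly half of births
#' from the second half of December 2020 onwards were conceived after the
#' mid-March 2020 lockdowns: monthly series are exposed from 2020-12 for 13
#' months (through 2021-12), weekly series from 2020-W51 for 54 weeks (through
#' 2021-W51). A shock window is a level-shift dummy absorbing a known
#' transient disturbance (e.g. the Zika epidemic, August-December 2016) so it
#' does not contaminate the trend.
#'
#' @param start,end period labels bounding the window (inclusive).
#' @param label name for the shock indicator column.
#' @param frequency `"weekly"` or `"monthly"`.
#' @return An object of class `"exposure_window"` or `"shock_window"` with
#'   elements `start`, `end` (and `label` for shocks).
#' @examples
#' default_exposure_window("monthly")  # 2020-12 .. 2021-12, 13 months
#' default_exposure_window("weekly")   # 2020-W51 .. 2021-W51, 54 weeks
#' shock_window("zika", "2016-08", "2016-12")
#' @export
exposure_window <- function(start, end) {
  stopifnot(is.character(start), is.character(end),
            length(start) == 1L, length(end) == 1L)
  structure(list(start = start, end = end), class = "exposure_window")
}

#' @rdname exposure_window
#' @export
default_exposure_window <- function(frequency) {
  frequency <- match_frequency(frequency)
  if (frequency == "monthly") {
    exposure_window("2020-12", "2021-12")
  } else {
    exposure_window("2020-W51", period_add("2020-W51", 53L, "weekly"))
  }
}

#' @rdname exposure_window
#' @export
shock_window <- function(label, start, end) {
  stopifnot(is.character(label), length(label) == 1L)
  structure(list(label = label, start = start, end = end),
            class = "shock_window")
}

#' Specification of one group's interrupted-time-series regression
#'
#' Declares the regression structure fitted to each group's count series: a
#' quadratic secular trend on a centred/scaled sequential index, week- or
#' month-of-year fixed effects with the first period of the year as reference,
#' optional level-shift shock indicators, and a single exposure level-shift
#' indicator over the exposed window. No exposure (population-at-risk) offset
#' is used.
#'
#' @param frequency `"weekly"` or `"monthly"`.
#' @param exposure an [exposure_window()]; defaults to
#'   [default_exposure_window()] for the frequency.
#' @param shocks list of [shock_window()] objects (may be empty).
#' @param trend_degree polynomial degree of the secular trend (fixed at 2).
#' @return An object of class `"model_spec"`.
#' @examples
#' model_spec("monthly", shocks = list(shock_window("zika", "2016-08",
#'   "2016-12")))
#' @export
model_spec <- function(frequency,
                       exposure = default_exposure_window(frequency),
                       shocks = list(), trend_degree = 2L) {
  frequency <- match_frequency(frequency)
  stopifnot(inherits(exposure, "exposure_window"))
  if (trend_degree != 2L) {
    stop("trend_degree is fixed at 2 (linear + quadratic)", call. = FALSE)
  }
  if (length(shocks)) {
    stopifnot(all(vapply(shocks, inherits, TRUE, "shock_window")))
    labs <- vapply(shocks, `[[`, "", "label")
    if (anyDuplicated(labs)) stop("duplicate shock labels", call. = FALSE)
    es <- period_start(exposure$start, frequency)
    ee <- period_start(exposure$end, frequency)
    for (sh in shocks) {
      if (period_start(sh$start, frequency) <= ee &&
          period_start(sh$end, frequency) >= es) {
        stop("shock window '", sh$label,
             "' overlaps the exposure window", call. = FALSE)
      }
    }
  }
  structure(list(frequency = frequency, trend_degree = 2L,
                 exposure = exposure, shocks = shocks),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("ITS Poisson model spec (%s)\n", x$frequency))
  cat("  trend: linear + quadratic (centred/scaled index)\n")
  cat(sprintf("  seasonality: %s-of-year fixed effects, reference = first %s\n",
              if (x$frequency == "weekly") "week" else "month",
              if (x$frequency == "weekly") "week" else "month"))
  cat(sprintf("  exposure: %s .. %s\n", x$exposure$start, x$exposure$end))
  for (sh in x$shocks) {
    cat(sprintf("  shock '%s': %s .. %s\n", sh$label, sh$start, sh$end))
  }
  invisible(x)
}

window_flag <- function(periods, frequency, start, end) {
  s <- period_start(periods, frequency)
  s >= period_start(start, frequency) & s <= period_start(end, frequency)
}

#' Seasonal level of each period (week 53 merged with week 52)
#'
#' ISO week 53 occurs in only a few years of any span, so its seasonal
#' indicator would be estimated from one or two observations; its level is
#' merged with week 52.
#' @noRd
seasonal_level <- function(periods, frequency) {
  poy <- period_of_year(periods, frequency)
  if (frequency == "weekly") poy[poy == 53L] <- 52L
  poy
}

#' Build the regression design matrix for an ITS Poisson model
#'
#' Columns, in order: `(Intercept)`; `t_lin` = (t - mean(t)) / T and
#' `t_quad` = t_lin^2 where t is the 0-based period index and T the number of
#' periods (centring/scaling keeps the quadratic term well conditioned); one
#' indicator `season_k` per non-reference week/month of year present in the
#' span (reference = week/month 1; ISO week 53 is merged with week 52); one
#' indicator per shock window; and the `exposure` indicator. There is no
#' offset column. Seasonal levels absent from the span are dropped with a
#' warning.
#'
#' @param series a [grouped_count_series()].
#' @param spec a [model_spec()] with the same frequency.
#' @return A numeric matrix with named columns and a `"term_type"` attribute
#'   classifying each column as `"intercept"`, `"trend"`, `"season"`,
#'   `"shock"` or `"exposure"`.
#' @examples
#' s <- grouped_count_series(
#'   matrix(5L, 24, 1, dimnames = list(period_seq("2020-01", "2021-12",
#'     "monthly"), "all")),
#'   "monthly", exposure_window("2020-12", "2021-12"))
#' ncol(build_design_matrix(s, model_spec("monthly")))  # 15
#' @export
build_design_matrix <- function(series, spec) {
  stopifnot(inherits(series, "grouped_count_series"),
            inherits(spec, "model_spec"))
  if (series$frequency != spec$frequency) {
    stop("series and spec frequencies differ", call. = FALSE)
  }
  periods <- series$periods
  n <- length(periods)
  t0 <- series$t
  t_lin <- (t0 - mean(t0)) / n
  X <- cbind(`(Intercept)` = rep(1, n), t_lin = t_lin, t_quad = t_lin^2)
  types <- c("intercept", "trend", "trend")

  lev <- seasonal_level(periods, spec$frequency)
  max_lev <- if (spec$frequency == "weekly") 52L else 12L
  wanted <- setdiff(2L:max_lev, integer(0))
  present <- wanted[wanted %in% lev]
  absent <- setdiff(wanted, present)
  if (length(absent)) {
    warning("seasonal level(s) absent from span, column(s) dropped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  if (length(present)) {
    S <- vapply(present, function(k) as.numeric(lev == k), numeric(n))
    colnames(S) <- paste0("season_", present)
    X <- cbind(X, S)
    types <- c(types, rep("season", length(present)))
  }

  for (sh in spec$shocks) {
    flag <- window_flag(periods, spec$frequency, sh$start, sh$end)
    if (!any(flag)) {
      stop("shock window '", sh$label, "' outside series span", call. = FALSE)
    }
    X <- cbind(X, as.numeric(flag))
    colnames(X)[ncol(X)] <- sh$label
    types <- c(types, "shock")
  }

  es <- period_start(spec$exposure$start, spec$frequency)
  ee <- period_start(spec$exposure$end, spec$frequency)
  starts <- period_start(periods, spec$frequency)
  if (es < starts[1L] || ee > starts[n]) {
    stop("exposure window extends beyond the series span", call. = FALSE)
  }
  eflag <- starts >= es & starts <= ee
  if (!any(eflag)) stop("exposure window is empty", call. = FALSE)
  X <- cbind(X, exposure = as.numeric(eflag))
  types <- c(types, "exposure")

  attr(X, "term_type") <- stats::setNames(types, colnames(X))
  X
}
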