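#' Observed per-period group proportions
#'
#' Each group's share of all births in each period (the descriptive
#' proportions-over-time display that motivates the compositional analysis).
#'
#' @param series a [grouped_count_series()].
#' @return Data frame with columns `period`, `group`, `proportion`.
#' @export
proportion_series <- function(series) {
  stopifnot(inherits(series, "grouped_count_series"))
  tot <- rowSums(series$counts)
  if (any(tot == 0)) {
    stop("zero total births in period(s): ",
         paste(series$periods[tot == 0], collapse = ", "), call. = FALSE)
  }
  data.frame(
    period = rep(series$periods, times = length(series$groups)),
    group = rep(series$groups, each = length(series$periods)),
    proportion = as.numeric(series$counts / tot),
    stringsAsFactors = FALSE
  )
}

#' Read and validate a pipeline configuration
#'
#' The pipeline is driven by a single YAML document with fields:
#' \describe{
#'   \item{frequency}{`"weekly"` or `"monthly"`.}
#'   \item{input}{exactly one of `scenario` (path to a scenario YAML, see
#'     [write_scenario()]), `counts` (CSV `period,group,count`) or `records`
#'     (CSV with `date_of_birth` and grouping fields).}
#'   \item{group_rule}{for records input: either `column: <name>` or
#'     `quintiles: {score_column: <name>}` (quintile cutpoints from the
#'     pre-exposure records only).}
#'   \item{filters}{for records input: list of predicate strings, e.g.
#'     `"maternal_age > 25"`.}
#'   \item{exposure}{`{start, end}` period labels; default the frequency's
#'     standard window.}
#'   \item{shocks}{list of `{label, start, end}` level-shift windows.}
#'   \item{n_draws, seed, truncate_at_zero}{Monte-Carlo settings (defaults
#'     10000, 1, false).}
#'   \item{out_dir}{output directory.}
#'   \item{figures}{write PNG figures (default true).}
#' }
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return A validated list of class `"analysis_config"`.
#' @export
read_analysis_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a file path or a list", call. = FALSE)
  cfg$frequency <- match_frequency(cfg$frequency)
  sources <- intersect(names(cfg$input), c("scenario", "counts", "records"))
  if (length(sources) != 1L) {
    stop("config must name exactly one input source ",
         "(scenario, counts or records)", call. = FALSE)
  }
  cfg$input_kind <- sources
  cfg$n_draws <- if (is.null(cfg$n_draws)) 10000L else as.integer(cfg$n_draws)
  if (cfg$n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$truncate_at_zero <- isTRUE(cfg$truncate_at_zero)
  cfg$figures <- if (is.null(cfg$figures)) TRUE else isTRUE(cfg$figures)
  if (is.null(cfg$out_dir)) stop("config must set out_dir", call. = FALSE)
  exposure <- if (is.null(cfg$exposure)) {
    default_exposure_window(cfg$frequency)
  } else {
    exposure_window(cfg$exposure$start, cfg$exposure$end)
  }
  shocks <- lapply(cfg$shocks, function(sh) {
    shock_window(sh$label, sh$start, sh$end)
  })
  cfg$spec <- model_spec(cfg$frequency, exposure = exposure, shocks = shocks)
  class(cfg) <- "analysis_config"
  cfg
}

pipeline_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  invisible(NULL)
}

load_pipeline_series <- function(cfg, quiet) {
  exposure <- cfg$spec$exposure
  switch(cfg$input_kind,
    scenario = {
      scenario <- read_scenario(cfg$input$scenario)
      pipeline_log(quiet, "simulate", "scenario '%s', seed %d",
                   cfg$input$scenario, cfg$seed)
      generate_group_series(scenario, seed = cfg$seed)
    },
    counts = read_count_series(cfg$input$counts, cfg$frequency, exposure),
    records = {
      rec <- utils::read.csv(cfg$input$records, stringsAsFactors = FALSE)
      n0 <- nrow(rec)
      for (f in cfg$filters) {
        keep <- eval(str2lang(f), rec, baseenv())
        keep[is.na(keep)] <- FALSE
        rec <- rec[keep, , drop = FALSE]
      }
      pipeline_log(quiet, "build", "filters kept %d of %d records",
                   nrow(rec), n0)
      if (nrow(rec) == 0L) stop("no records left after filtering",
                                call. = FALSE)
      rule <- NULL
      gr <- cfg$group_rule
      if (!is.null(gr$quintiles)) {
        scol <- gr$quintiles$score_column
        rule <- function(r) {
          pre <- period_start(date_to_period(as.Date(r$date_of_birth),
                                             cfg$frequency), cfg$frequency) <
            period_start(exposure$start, cfg$frequency)
          assign_quintiles(r[[scol]], r[[scol]][pre])
        }
      } else if (!is.null(gr$column) && gr$column != "group") {
        rule <- function(r) r[[gr$column]]
      }
      aggregate_records(rec, cfg$frequency, group_rule = rule,
                        exposure = exposure)
    }
  )
}

#' Run the full counterfactual-composition pipeline
#'
#' simulate/load, build, fit and compose in one call, writing every tabular
#' result as CSV, optional PNG figures mirroring the standard displays
#' (per-group trajectories with counterfactual dashed line and exposure rule;
#' proportions over time; delta dot-and-CI chart), and a JSON run manifest
#' with the configuration hash and all design flags in effect. Deterministic:
#' identical configuration (including seed) reproduces byte-identical CSVs.
#'
#' Files written to `out_dir`: `counts.csv`, `fit_summary.csv`
#' (`group,term,estimate,se`), `paths.csv`
#' (`period,group,series,value`, series one of observed / fitted /
#' deseasonalised / counterfactual), `composition.csv`, `relative.csv`,
#' `proportions.csv`, `manifest.json`, and under `figures/` one PNG per
#' group plus `proportions.png` and `composition.png`.
#'
#' @param config path to a YAML configuration, a list, or an
#'   `"analysis_config"` (see [read_analysis_config()]).
#' @param out_dir overrides the configured output directory.
#' @param quiet suppress per-stage log messages.
#' @return Invisibly, a list with the `series`, the fitted
#'   [cohort_composition()] object, the written file paths and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- if (inherits(config, "analysis_config")) config else
    read_analysis_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  out <- function(name) file.path(cfg$out_dir, name)

  series <- withCallingHandlers(
    load_pipeline_series(cfg, quiet),
    error = function(e) stop("stage 'build' failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  write_count_series(series, out("counts.csv"))
  paths <- c(paths, out("counts.csv"))

  fit <- tryCatch(
    cohort_composition(series, spec = cfg$spec, n_draws = cfg$n_draws,
                       seed = cfg$seed,
                       truncate_at_zero = cfg$truncate_at_zero),
    error = function(e) stop("stage 'fit/compose' failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  for (g in names(fit$fits)) {
    pipeline_log(quiet, "fit", "group=%s periods=%d converged=%s", g,
                 length(fit$fits[[g]]$y), fit$fits[[g]]$converged)
  }

  fit_summary <- do.call(rbind, lapply(names(fit$fits), function(g) {
    f <- fit$fits[[g]]
    data.frame(group = g, term = names(f$coefficients),
               estimate = as.numeric(f$coefficients),
               se = sqrt(diag(f$vcov)), stringsAsFactors = FALSE)
  }))
  utils::write.csv(fit_summary, out("fit_summary.csv"), row.names = FALSE,
                   quote = FALSE)

  paths_df <- do.call(rbind, lapply(names(fit$fits), function(g) {
    f <- fit$fits[[g]]
    exposed <- exposure_flag_from_fit(f)
    cfp <- counterfactual_path(f, type = "deseasonalised")
    rbind(
      data.frame(period = f$periods, group = g, series = "observed",
                 value = f$y),
      data.frame(period = f$periods, group = g, series = "fitted",
                 value = f$fitted_means),
      data.frame(period = f$periods, group = g, series = "deseasonalised",
                 value = deseasonalise(f)),
      data.frame(period = f$periods[exposed], group = g,
                 series = "counterfactual", value = as.numeric(cfp))
    )
  }))
  utils::write.csv(paths_df, out("paths.csv"), row.names = FALSE,
                   quote = FALSE)

  comp_df <- as.data.frame(fit$composition)
  utils::write.csv(comp_df, out("composition.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fit$relative, out("relative.csv"), row.names = FALSE,
                   quote = FALSE)
  props <- proportion_series(series)
  utils::write.csv(props, out("proportions.csv"), row.names = FALSE,
                   quote = FALSE)
  paths <- c(paths, out(c("fit_summary.csv", "paths.csv", "composition.csv",
                          "relative.csv", "proportions.csv")))
  pipeline_log(quiet, "compose", "%d groups, %d draws, seed %d",
               nrow(comp_df), cfg$n_draws, cfg$seed)

  if (cfg$figures) {
    figdir <- out("figures")
    dir.create(figdir, showWarnings = FALSE)
    try_figure <- function(file, expr) {
      ok <- tryCatch({
        grDevices::png(file, width = 1400, height = 700, res = 130)
        on.exit(grDevices::dev.off(), add = TRUE)
        expr()
        TRUE
      }, error = function(e) {
        warning("figure '", basename(file), "' skipped: ",
                conditionMessage(e), call. = FALSE)
        FALSE
      })
      if (ok) paths <<- c(paths, file)
    }
    for (g in names(fit$fits)) {
      f <- fit$fits[[g]]
      try_figure(file.path(figdir, paste0("fit_", g, ".png")),
                 function() plot(f))
    }
    try_figure(file.path(figdir, "proportions.png"), function() {
      plot_proportions(props, series)
    })
    try_figure(file.path(figdir, "composition.png"), function() {
      plot(fit$composition)
    })
  }

  manifest <- list(
    package = "cohortcomp",
    package_version = as.character(utils::packageVersion("cohortcomp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = config_hash(cfg),
    frequency = cfg$frequency,
    input_kind = cfg$input_kind,
    exposure = list(start = cfg$spec$exposure$start,
                    end = cfg$spec$exposure$end,
                    n_exposed = sum(series$exposure)),
    shocks = lapply(cfg$spec$shocks, function(sh) {
      list(label = sh$label, start = sh$start, end = sh$end)
    }),
    n_draws = cfg$n_draws,
    seed = cfg$seed,
    design_flags = list(
      truncate_at_zero = cfg$truncate_at_zero,
      week53_merged_with_week52 = (cfg$frequency == "weekly"),
      counterfactual_totals_retain_seasonality = TRUE,
      counterfactual_se = "delta_method",
      percentile_type = 7L
    ),
    groups = names(fit$fits),
    converged = vapply(fit$fits, `[[`, TRUE, "converged")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  paths <- c(paths, out("manifest.json"))

  invisible(list(series = series, fit = fit, paths = paths,
                 manifest = manifest))
}

plot_proportions <- function(props, series) {
  n <- length(series$periods)
  idx <- seq_len(n)
  groups <- series$groups
  cols <- grDevices::hcl.colors(max(length(groups), 3L), "Dark 3")
  graphics::plot(NULL, xlim = c(1, n),
                 ylim = range(props$proportion), xlab = "period",
                 ylab = "proportion of live births", xaxt = "n",
                 main = "Observed group shares over time")
  at <- pretty(idx); at <- at[at >= 1 & at <= n]
  graphics::axis(1, at = at, labels = series$periods[at], las = 2,
                 cex.axis = 0.7)
  for (i in seq_along(groups)) {
    p <- props$proportion[props$group == groups[i]]
    graphics::lines(idx, p, col = cols[i])
  }
  if (any(series$exposure)) {
    graphics::abline(v = min(idx[series$exposure]), col = "grey30")
  }
  graphics::legend("topleft", legend = groups, col = cols[seq_along(groups)],
                   lty = 1, bty = "n", cex = 0.8)
}

config_hash <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), c("spec"))]
  keep <- keep[order(names(keep))]
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(keep, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
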