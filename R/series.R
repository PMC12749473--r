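#' Grouped live-birth count series
#'
#' The central data container: a complete weekly or monthly time series of
#' live-birth counts per socioeconomic group, with a 0-based sequential index
#' and an exposure flag marking the pandemic-conception birth cohort window.
#'
#' @param counts either a numeric matrix of counts (rows = periods, with
#'   rownames giving period labels; columns = groups, with colnames), or a long
#'   data frame with columns `period`, `group`, `count`.
#' @param frequency `"weekly"` or `"monthly"`.
#' @param exposure an [exposure_window()] (or `NULL` for no exposed periods).
#'
#' @details Periods must be contiguous with no gaps or duplicates; every group
#'   is present for every period (missing combinations in long input are
#'   zero-filled). The exposure flag is a single contiguous block of periods.
#'
#' @return An object of class `"grouped_count_series"`: a list with elements
#'   `frequency`, `periods`, `t` (0-based index), `counts` (periods x groups
#'   integer matrix), `groups`, `exposure` (logical per period) and
#'   `exposure_window`.
#' @examples
#' m <- matrix(5L, 4, 2, dimnames = list(period_seq("2020-11", "2021-02",
#'   "monthly"), c("Q1", "Q5")))
#' s <- grouped_count_series(m, "monthly",
#'   exposure_window("2020-12", "2021-02"))
#' s$exposure
#' @export
grouped_count_series <- function(counts, frequency, exposure = NULL) {
  frequency <- match_frequency(frequency)
  if (is.data.frame(counts)) {
    need <- c("period", "group", "count")
    if (!all(need %in% names(counts))) {
      stop("long input needs columns period, group, count", call. = FALSE)
    }
    if (anyDuplicated(counts[c("period", "group")])) {
      stop("duplicate (period, group) rows in count table", call. = FALSE)
    }
    periods <- period_seq(min_period(counts$period, frequency),
                          max_period(counts$period, frequency), frequency)
    groups <- sort(unique(as.character(counts$group)))
    m <- matrix(0L, length(periods), length(groups),
                dimnames = list(periods, groups))
    m[cbind(match(counts$period, periods),
            match(as.character(counts$group), groups))] <- counts$count
    counts <- m
  }
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts))) {
    stop("'counts' must be a matrix with period rownames and group colnames",
         call. = FALSE)
  }
  periods <- rownames(counts)
  full <- period_seq(periods[1L], periods[length(periods)], frequency)
  if (!identical(periods, full)) {
    stop("periods must be contiguous and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  flag <- rep(FALSE, length(periods))
  if (!is.null(exposure)) {
    stopifnot(inherits(exposure, "exposure_window"))
    starts <- period_start(periods, frequency)
    flag <- starts >= period_start(exposure$start, frequency) &
      starts <= period_start(exposure$end, frequency)
    if (!any(flag)) {
      stop("exposure window lies outside the series span", call. = FALSE)
    }
    if (period_start(exposure$start, frequency) < starts[1L] ||
        period_start(exposure$end, frequency) > starts[length(starts)]) {
      stop("exposure window extends beyond the series span", call. = FALSE)
    }
  }
  structure(
    list(frequency = frequency, periods = periods,
         t = seq_along(periods) - 1L, counts = counts,
         groups = colnames(counts), exposure = flag,
         exposure_window = exposure),
    class = "grouped_count_series"
  )
}

min_period <- function(x, frequency) x[which.min(period_start(x, frequency))]
max_period <- function(x, frequency) x[which.max(period_start(x, frequency))]

#' @export
print.grouped_count_series <- function(x, ...) {
  cat(sprintf("Grouped %s live-birth count series\n", x$frequency))
  cat(sprintf("  %d periods: %s .. %s\n", length(x$periods),
              x$periods[1L], x$periods[length(x$periods)]))
  cat(sprintf("  %d groups: %s\n", length(x$groups),
              paste(x$groups, collapse = ", ")))
  if (any(x$exposure)) {
    cat(sprintf("  exposed: %d periods (%s .. %s)\n", sum(x$exposure),
                x$periods[which(x$exposure)[1L]],
                x$periods[max(which(x$exposure))]))
  } else {
    cat("  exposed: none\n")
  }
  cat(sprintf("  total births: %s\n", format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.grouped_count_series <- function(x, ...) {
  data.frame(
    period = rep(x$periods, times = length(x$groups)),
    group = rep(x$groups, each = length(x$periods)),
    count = as.integer(x$counts),
    exposed = rep(x$exposure, times = length(x$groups)),
    stringsAsFactors = FALSE
  )
}

#' Read and write grouped count series as CSV
#'
#' Long CSV with header `period,group,count`; periods formatted `YYYY-Www`
#' (ISO week) or `YYYY-MM`.
#'
#' @param file path to a CSV file.
#' @param frequency `"weekly"` or `"monthly"`.
#' @param exposure an [exposure_window()] or `NULL`.
#' @param x a [grouped_count_series()].
#' @return `read_count_series()` returns a [grouped_count_series()];
#'   `write_count_series()` invisibly returns `file`.
#' @export
read_count_series <- function(file, frequency, exposure = NULL) {
  df <- utils::read.csv(file, colClasses = c("character", "character",
                                             "integer"))
  grouped_count_series(df, frequency, exposure)
}

#' @rdname read_count_series
#' @export
write_count_series <- function(x, file) {
  stopifnot(inherits(x, "grouped_count_series"))
  df <- as.data.frame(x)
  utils::write.csv(df[c("period", "group", "count")], file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Aggregate individual birth records into a grouped count series
#'
#' Bins birth records into ISO weeks or calendar months and tallies counts per
#' (period, group), zero-filling missing combinations. The period span runs
#' from the earliest to the latest record period unless `periods` forces a
#' wider span.
#'
#' @param records a data frame with columns `date_of_birth` (Date or
#'   `YYYY-MM-DD` strings) and, unless `group_rule` is supplied, `group`.
#' @param frequency `"weekly"` or `"monthly"`.
#' @param group_rule optional function mapping the records data frame to a
#'   character vector of group labels (for example a quintile assignment from
#'   a continuous score); defaults to `records$group`.
#' @param periods optional character vector of period labels fixing the span.
#' @param exposure an [exposure_window()] or `NULL`.
#' @return A [grouped_count_series()].
#' @examples
#' rec <- data.frame(date_of_birth = as.Date("2020-12-14"), group = "Q5")
#' aggregate_records(rec, "weekly")$periods  # "2020-W51"
#' @export
aggregate_records <- function(records, frequency, group_rule = NULL,
                              periods = NULL, exposure = NULL) {
  frequency <- match_frequency(frequency)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data frame", call. = FALSE)
  }
  dates <- as.Date(records$date_of_birth)
  if (anyNA(dates)) {
    stop("unparseable date_of_birth at record(s): ",
         paste(utils::head(which(is.na(dates)), 5L), collapse = ", "),
         call. = FALSE)
  }
  labels <- if (is.null(group_rule)) {
    if (is.null(records$group)) stop("records lack a 'group' column and no group_rule given", call. = FALSE)
    as.character(records$group)
  } else {
    as.character(group_rule(records))
  }
  per <- date_to_period(dates, frequency)
  if (is.null(periods)) {
    periods <- period_seq(min_period(per, frequency),
                          max_period(per, frequency), frequency)
  }
  groups <- sort(unique(labels))
  tab <- table(factor(per, levels = periods), factor(labels, levels = groups))
  m <- matrix(as.integer(tab), nrow = length(periods),
              dimnames = list(periods, groups))
  if (sum(m) != nrow(records)) {
    stop("some records fall outside the supplied period span", call. = FALSE)
  }
  grouped_count_series(m, frequency, exposure)
}

#' Assign quintile labels from a pre-pandemic reference distribution
#'
#' Cutpoints are the 20/40/60/80 percentiles of the *reference* scores only
#' (pre-pandemic incomes or deprivation scores), so pandemic-era shifts in the
#' score distribution cannot move group boundaries. Values equal to a cutpoint
#' go to the lower quintile; values outside the reference range are clamped to
#' Q1/Q5. `Q5` is the highest score (highest income / least deprived).
#'
#' @param values numeric scores to label; `NA` entries get `missing_label`.
#' @param reference numeric vector of pre-pandemic scores defining cutpoints.
#' @param missing_label label for missing scores (default `"missing"`).
#' @return Character vector of labels `"Q1"`..`"Q5"` or `missing_label`.
#' @examples
#' table(assign_quintiles(1:100, 1:100))
#' @export
assign_quintiles <- function(values, reference, missing_label = "missing") {
  reference <- reference[!is.na(reference)]
  if (length(reference) == 0L) {
    stop("reference distribution is empty or all-missing", call. = FALSE)
  }
  cuts <- stats::quantile(reference, probs = c(.2, .4, .6, .8), names = FALSE,
                          type = 7)
  out <- rep(missing_label, length(values))
  ok <- !is.na(values)
  # left-closed: a value equal to a cutpoint stays in the lower quintile
  idx <- rowSums(outer(values[ok], cuts, ">")) + 1L
  out[ok] <- paste0("Q", idx)
  out
}

#' Filter birth records by a predicate on record fields
#'
#' @param records a data frame of birth records.
#' @param predicate an unquoted expression over record columns, e.g.
#'   `maternal_age > 25` (strictly greater). Missing predicate returns the
#'   records unchanged. Rows where the predicate is `NA` are dropped.
#' @param quiet suppress the message reporting how many records were removed.
#' @return The filtered data frame.
#' @examples
#' rec <- data.frame(date_of_birth = Sys.Date() + 0:2,
#'                   group = "A", maternal_age = c(24, 25, 26))
#' filter_records(rec, maternal_age > 25)  # keeps only age 26
#' @export
filter_records <- function(records, predicate, quiet = FALSE) {
  if (missing(predicate)) return(records)
  expr <- substitute(predicate)
  used <- all.vars(expr)
  absent <- setdiff(used, names(records))
  if (length(absent)) {
    stop("predicate references absent field(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  keep <- eval(expr, records, parent.frame())
  if (!is.logical(keep) || length(keep) != nrow(records)) {
    stop("predicate must evaluate to one logical per record", call. = FALSE)
  }
  keep[is.na(keep)] <- FALSE
  if (!quiet) {
    message(sprintf("filter_records: removed %d of %d records",
                    sum(!keep), nrow(records)))
  }
  records[keep, , drop = FALSE]
}
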