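#' Calendar period utilities
#'
#' Analysis periods are either ISO-8601 weeks (labels `"YYYY-Www"`, weeks start
#' on Monday) or calendar months (labels `"YYYY-MM"`). Internally every period
#' is anchored at its start date: the Monday of the ISO week or the first day
#' of the month. ISO weeks are the standard aggregation unit of European vital
#' registers; years contain 52 or 53 weeks.
#'
#' @param x character vector of period labels.
#' @param frequency `"weekly"` or `"monthly"`.
#' @return `period_start()` returns a `Date` vector; `date_to_period()` a
#'   character vector of labels; `period_of_year()` an integer vector (ISO week
#'   number or month number).
#' @examples
#' date_to_period(as.Date("2020-12-14"), "weekly")   # "2020-W51"
#' period_start("2021-03", "monthly")                # 2021-03-01
#' period_of_year("2020-W53", "weekly")              # 53
#' @name periods
NULL

match_frequency <- function(frequency) {
  match.arg(frequency, c("weekly", "monthly"))
}

#' @rdname periods
#' @export
period_start <- function(x, frequency) {
  frequency <- match_frequency(frequency)
  if (frequency == "monthly") {
    ok <- grepl("^\\d{4}-\\d{2}$", x) &
      as.integer(substr(x, 6L, 7L)) %in% 1:12
    if (!all(ok)) {
      stop("malformed monthly period label(s): ",
           paste(x[!ok], collapse = ", "), call. = FALSE)
    }
    return(as.Date(paste0(x, "-01")))
  }
  ok <- grepl("^\\d{4}-W\\d{2}$", x)
  if (!all(ok)) {
    stop("malformed weekly period label(s): ",
         paste(x[!ok], collapse = ", "), call. = FALSE)
  }
  year <- as.integer(substr(x, 1L, 4L))
  week <- as.integer(substr(x, 7L, 8L))
  # Jan 4 always falls in ISO week 1; step back to its Monday.
  jan4 <- as.Date(sprintf("%d-01-04", year))
  week1 <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  out <- week1 + (week - 1L) * 7L
  bad <- week < 1L | format(out, "%G-W%V") != x
  if (any(bad)) {
    stop("invalid ISO week label(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname periods
#' @param dates a `Date` vector (or values coercible with `as.Date`).
#' @export
date_to_period <- function(dates, frequency) {
  frequency <- match_frequency(frequency)
  dates <- as.Date(dates)
  if (anyNA(dates)) {
    stop("unparseable date at position(s): ",
         paste(which(is.na(dates)), collapse = ", "), call. = FALSE)
  }
  if (frequency == "weekly") format(dates, "%G-W%V") else format(dates, "%Y-%m")
}

#' @rdname periods
#' @export
period_of_year <- function(x, frequency) {
  frequency <- match_frequency(frequency)
  period_start(x, frequency)  # validates
  if (frequency == "weekly") {
    as.integer(substr(x, 7L, 8L))
  } else {
    as.integer(substr(x, 6L, 7L))
  }
}

#' Sequences and arithmetic on period labels
#'
#' @param from,to period labels bounding the (inclusive) sequence.
#' @param x a period label.
#' @param n integer number of periods to step (may be negative).
#' @param frequency `"weekly"` or `"monthly"`.
#' @return `period_seq()` returns the ordered vector of all period labels from
#'   `from` to `to`; `period_add()` the label `n` periods after `x`.
#' @examples
#' period_seq("2020-W51", "2021-W02", "weekly")
#' period_add("2020-12", 12, "monthly")  # "2021-12"
#' @export
period_seq <- function(from, to, frequency) {
  frequency <- match_frequency(frequency)
  a <- period_start(from, frequency)
  b <- period_start(to, frequency)
  if (a > b) stop("'from' is after 'to'", call. = FALSE)
  if (frequency == "weekly") {
    format(seq(a, b, by = 7L), "%G-W%V")
  } else {
    format(seq(a, b, by = "month"), "%Y-%m")
  }
}

#' @rdname period_seq
#' @export
period_add <- function(x, n, frequency) {
  frequency <- match_frequency(frequency)
  a <- period_start(x, frequency)
  n <- as.integer(n)
  if (frequency == "weekly") {
    format(a + 7L * n, "%G-W%V")
  } else if (n == 0L) {
    format(a, "%Y-%m")
  } else {
    format(seq(a, by = sprintf("%d months", n), length.out = 2L)[2L], "%Y-%m")
  }
}
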