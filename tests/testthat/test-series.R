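test_that("records bin into the correct periods and zero-fill the span", {
  rec <- data.frame(
    date_of_birth = as.Date(c("2020-12-14", "2020-12-20", "2021-01-04")),
    group = c("A", "B", "A")
  )
  s <- aggregate_records(rec, "weekly")
  expect_identical(s$periods, c("2020-W51", "2020-W52", "2020-W53",
                                "2021-W01"))
  expect_identical(s$counts["2020-W51", ], c(A = 1L, B = 1L))
  expect_identical(s$counts["2020-W52", ], c(A = 0L, B = 0L))  # zero-filled
  expect_identical(s$counts["2021-W01", "A"], 1L)
  expect_identical(sum(s$counts), 3L)

  m <- aggregate_records(data.frame(date_of_birth = "2021-03-05",
                                    group = "A"), "monthly")
  expect_identical(m$periods, "2021-03")
})

test_that("aggregation errors name the offending record", {
  rec <- data.frame(date_of_birth = c("2020-01-01", "not-a-date"),
                    group = "A")
  expect_error(aggregate_records(rec, "monthly"), "record\\(s\\): 2")
  expect_error(aggregate_records(data.frame(), "monthly"), "non-empty")
})

test_that("total aggregated count equals number of records under any group rule", {
  sc <- demo_scenario("monthly")
  rec <- generate_birth_records(sc, seed = 11L)
  s <- aggregate_records(rec, "monthly")
  expect_identical(sum(s$counts), nrow(rec))
  s2 <- aggregate_records(rec, "monthly",
                          group_rule = function(r) {
                            ifelse(r$group == "missing", "missing", "known")
                          })
  expect_identical(sum(s2$counts), nrow(rec))
  expect_identical(sort(s2$groups), c("known", "missing"))
})

test_that("quintile cutpoints come from the reference distribution only", {
  q <- assign_quintiles(1:100, 1:100)
  expect_identical(as.integer(table(q)[paste0("Q", 1:5)]), rep(20L, 5))
  # below the reference minimum -> Q1; above its maximum -> Q5
  expect_identical(assign_quintiles(c(-5, 0.5), 1:100), c("Q1", "Q1"))
  expect_identical(assign_quintiles(c(101, 102), 1:100), c("Q5", "Q5"))
  # a value equal to a cutpoint stays in the lower quintile
  ref <- rep(1:5, each = 20)  # 20/40/60/80 percentiles: 1.8, 2.6, 3.4, 4.2
  expect_identical(assign_quintiles(c(1.8, 1.81), ref), c("Q1", "Q2"))
  # missing values get the missing label; all-missing reference errors
  expect_identical(assign_quintiles(c(NA, 3), 1:100), c("missing", "Q1"))
  expect_error(assign_quintiles(1, c(NA_real_, NA_real_)), "all-missing")
})

test_that("record filters apply strict predicates and report removals", {
  rec <- data.frame(date_of_birth = Sys.Date() + 0:2, group = "A",
                    maternal_age = c(24, 25, 26))
  expect_message(out <- filter_records(rec, maternal_age > 25),
                 "removed 2 of 3")
  expect_identical(out$maternal_age, 26)
  expect_identical(filter_records(rec), rec)
  expect_error(filter_records(rec, parity >= 2), "absent field")
})

test_that("design matrix has the documented columns and full rank", {
  sc <- demo_scenario("monthly")
  series <- generate_group_series(sc)
  X <- build_design_matrix(series, model_spec("monthly"))
  # 1 intercept + 2 trend + 11 seasonal + 1 exposure
  expect_identical(ncol(X), 15L)
  expect_identical(colnames(X)[1:3], c("(Intercept)", "t_lin", "t_quad"))
  expect_identical(colnames(X)[ncol(X)], "exposure")
  expect_identical(qr(X)$rank, ncol(X))
  expect_identical(sum(X[, "exposure"]), 13)
  tt <- attr(X, "term_type")
  expect_identical(as.integer(table(tt)[c("season", "trend")]), c(11L, 2L))
  # trend columns are centred and scaled
  expect_equal(sum(X[, "t_lin"]), 0, tolerance = 1e-10)
  expect_lt(max(abs(X[, "t_lin"])), 0.5)
})

test_that("weekly design merges week 53 with week 52 and spans 51 seasonal columns", {
  sw <- generate_group_series(demo_scenario("weekly"))
  X <- build_design_matrix(sw, model_spec("weekly"))
  tt <- attr(X, "term_type")
  expect_identical(sum(tt == "season"), 51L)
  expect_false("season_53" %in% colnames(X))
  # 2015 and 2020 both contain ISO week 53; their rows load on season_52
  w53 <- period_of_year(sw$periods, "weekly") == 53L
  expect_true(all(X[w53, "season_52"] == 1))
  expect_identical(qr(X)$rank, ncol(X))
  expect_identical(sum(X[, "exposure"]), 54)
})

test_that("two full years with weeks 1-52 only give 51 seasonal indicators", {
  periods <- period_seq("2018-W01", "2019-W52", "weekly")
  m <- matrix(5L, length(periods), 1, dimnames = list(periods, "all"))
  s <- grouped_count_series(m, "weekly")
  spec <- model_spec("weekly", exposure = exposure_window("2019-W40",
                                                          "2019-W52"))
  X <- build_design_matrix(s, spec)
  expect_identical(sum(attr(X, "term_type") == "season"), 51L)
})

test_that("design construction fails fast on inconsistent windows", {
  sc <- demo_scenario("monthly")
  series <- generate_group_series(sc)
  spec_out <- model_spec("monthly", exposure = exposure_window("2022-06",
                                                               "2022-12"))
  expect_error(build_design_matrix(series, spec_out), "beyond the series")
  expect_error(model_spec("monthly",
                          shocks = list(shock_window("x", "2021-01",
                                                     "2021-02"))),
               "overlaps the exposure")
  short <- grouped_count_series(
    matrix(5L, 6, 1, dimnames = list(period_seq("2020-10", "2021-03",
                                                "monthly"), "a")),
    "monthly")
  expect_warning(build_design_matrix(short, model_spec("monthly",
    exposure = exposure_window("2020-12", "2021-02"))), "absent from span")
})

test_that("series container enforces its invariants", {
  m <- matrix(1L, 3, 1,
              dimnames = list(c("2020-01", "2020-03", "2020-04"), "a"))
  expect_error(grouped_count_series(m, "monthly"), "contiguous")
  m2 <- matrix(c(1, -1), 2, 1,
               dimnames = list(c("2020-01", "2020-02"), "a"))
  expect_error(grouped_count_series(m2, "monthly"), "nonnegative")
  df <- data.frame(period = c("2020-01", "2020-01"), group = c("a", "a"),
                   count = 1:2)
  expect_error(grouped_count_series(df, "monthly"), "duplicate")
})

test_that("count series survive a CSV round-trip", {
  sc <- demo_scenario("monthly")
  series <- generate_group_series(sc)
  f <- withr::local_tempfile(fileext = ".csv")
  write_count_series(series, f)
  back <- read_count_series(f, "monthly", exposure = sc$exposure)
  expect_identical(back$counts[, sort(series$groups)],
                   series$counts[, sort(series$groups)])
  expect_identical(back$exposure, series$exposure)
})
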