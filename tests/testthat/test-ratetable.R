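test_that("expected hazard follows the attained age/year flooring rule", {
  tb <- const_table(0.02)
  expect_equal(expected_hazard(tb, 70, 2009, "male", 3.7), 0.02)

  # rate(70,2009)=0.01, rate(71,2010)=0.03: at t=1.5 both age and year floors
  # have advanced
  r <- array(0, c(2, 2, 1)); r[1, 1, 1] <- 0.01; r[2, 2, 1] <- 0.03
  tb2 <- rate_table(r, 70:71, 2009:2010, "m")
  expect_equal(expected_hazard(tb2, 70, 2009, "m", 1.5), 0.03)

  # clamping beyond the grid edge, with a warning
  tb3 <- rate_table(array(seq(0.01, 0.31, by = 0.01), c(31, 1, 1)),
                    60:90, 2009, "m")
  expect_warning(h <- expected_hazard(tb3, 99, 2009, "m", 0.5), "clamped")
  expect_equal(h, 0.31)
})

test_that("expected hazard rejects bad demographics and times", {
  tb <- const_table()
  expect_error(expected_hazard(tb, 70, 2009, "dog", 1), "dog")
  expect_error(expected_hazard(tb, 70, 2009, "male", NaN), "NA")
  expect_error(expected_hazard(tb, 70, 2009, "male", -1), "non-negative")
})

test_that("expected survival integrates the piecewise-constant rate exactly", {
  tb <- const_table(0.02)
  expect_equal(expected_survival(tb, 70, 2009, "male", 5), exp(-0.1),
               tolerance = 1e-12)
  expect_equal(expected_survival(tb, 70, 2009, "male", 0), 1)

  # 0.01 in the first attained-age year, 0.02 in the second
  r <- array(0.02, c(3, 3, 1)); r[1, , 1] <- 0.01
  tb2 <- rate_table(r, 70:72, 2009:2011, "m")
  expect_equal(expected_survival(tb2, 70, 2009, "m", 2), exp(-0.03),
               tolerance = 1e-12)
})

test_that("cumulative hazard matches a breakpoint-aligned Riemann oracle", {
  set.seed(1)
  for (rep in 1:5) {
    tb <- synthetic_ratetable(a = runif(1, 1e-4, 1e-2), b = runif(1, 0, 0.1),
                              years = 2005:2016, drift = 0.98, ages = 0:109)
    age <- runif(1, 40, 80); yr <- 2006 + runif(1); tmax <- runif(1, 3, 8)
    # oracle: subdivide finely BETWEEN the known integer crossings so the
    # midpoint sum of the piecewise-constant hazard is exact
    cross <- sort(unique(c(0, tmax,
                           seq(ceiling(age) - age, tmax, by = 1),
                           seq(ceiling(yr) - yr, tmax, by = 1))))
    grid <- unique(sort(unlist(lapply(seq_along(cross)[-1], function(i)
      seq(cross[i - 1], cross[i], length.out = 50)))))
    mids <- (grid[-1] + grid[-length(grid)]) / 2
    orac <- sum(expected_hazard(tb, age, yr, "male", mids) * diff(grid))
    expect_equal(expected_cumhaz(tb, age, yr, "male", tmax), orac,
                 tolerance = 1e-10)
  }
})

test_that("weights are inverse expected survival, >= 1 and non-decreasing", {
  tb <- const_table(0.02)
  tt <- seq(0, 20, by = 0.37)
  w <- expected_weight(tb, 70, 2009, "male", tt)
  S <- expected_survival(tb, 70, 2009, "male", tt)
  expect_equal(w * S, rep(1, length(tt)), tolerance = 1e-14)
  expect_true(all(w >= 1))
  expect_true(all(diff(w) >= 0))
  expect_equal(expected_weight(tb, 70, 2009, "male", 5), exp(0.1),
               tolerance = 1e-12)
})

test_that("synthetic rate tables follow the Gompertz form and cap", {
  tb <- synthetic_ratetable(a = 1e-4, b = 0, sex_ratio = 1)
  expect_true(all(tb$rate == 1e-4))
  tb2 <- synthetic_ratetable(a = 5e-5, b = 0.09)
  r80 <- expected_hazard(tb2, 80, 2009, "male", 0)
  r70 <- expected_hazard(tb2, 70, 2009, "male", 0)
  expect_equal(r80 / r70, exp(0.9), tolerance = 1e-12)
  tb3 <- synthetic_ratetable(a = 0.5, b = 0.09)     # explodes past the cap
  expect_equal(max(tb3$rate), 1)
  expect_error(synthetic_ratetable(a = -1), "positive")
})

test_that("rate table files round-trip and dialects convert correctly", {
  tb <- synthetic_ratetable(a = 1e-3, b = 0.05, years = 2008:2009,
                            ages = 60:62, sexes = c("male", "female"),
                            sex_ratio = 1.3)
  f <- tempfile(fileext = ".csv")
  write_ratetable(tb, f)
  tb2 <- read_ratetable(f)   # sexes come back in sorted order
  for (s in tb$sexes)
    expect_equal(tb2$rate[, , s], tb$rate[, , s], tolerance = 1e-12)

  # prob dialect: p = 0.99 -> rate -ln(0.99)
  df <- data.frame(sex = "m", year = 2009, age = c(60, 61),
                   prob = c(0.99, 0.98))
  f2 <- tempfile(fileext = ".csv")
  write.csv(df, f2, row.names = FALSE)
  tb3 <- read_ratetable(f2, dialect = "prob")
  expect_equal(expected_hazard(tb3, 60, 2009, "m", 0), -log(0.99),
               tolerance = 1e-12)
  # the dialect is explicit: reading the same file as rates must fail
  # (no rate column present)
  expect_error(read_ratetable(f2, dialect = "rate"), "rate")
})

test_that("gaps in a rate table file are reported by cell", {
  df <- expand.grid(sex = "m", year = 2009, age = 65:68)
  df$rate <- 0.01
  df <- df[df$age != 67, ]
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_error(read_ratetable(f), "age=67")
})

test_that("probabilities outside (0,1] are rejected", {
  df <- data.frame(sex = "m", year = 2009, age = 60, prob = 1.2)
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_error(read_ratetable(f, dialect = "prob"), "\\(0, 1\\]")
})
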