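#' Population rate table
#'
#' A rate table holds expected (population) mortality rates, in deaths per
#' person-year, on a complete grid of integer age, integer calendar year and
#' sex.  It supplies the expected hazard \eqn{h^*(t|X_i)} entering the additive
#' excess hazard decomposition \eqn{h(t|X_i) = h^*(t|X_i) + \lambda(t|X_i)}.
#'
#' @param rate numeric array of non-negative rates with dimensions
#'   `c(length(ages), length(years), length(sexes))`.
#' @param ages integer vector, a contiguous grid of ages in years.
#' @param years integer vector, a contiguous grid of calendar years.
#' @param sexes character vector of sex labels.
#' @return An object of class `rs_ratetable`.
#' @export
rate_table <- function(rate, ages, years, sexes) {
  ages <- as.integer(ages); years <- as.integer(years)
  sexes <- as.character(sexes)
  if (any(diff(ages) != 1L)) stop("`ages` must be a contiguous integer grid")
  if (any(diff(years) != 1L)) stop("`years` must be a contiguous integer grid")
  rate <- array(as.numeric(rate),
                dim = c(length(ages), length(years), length(sexes)),
                dimnames = list(ages, years, sexes))
  if (anyNA(rate) || any(!is.finite(rate)))
    stop("all rates must be finite and non-missing")
  if (any(rate < 0)) stop("all rates must be non-negative")
  structure(list(ages = ages, years = years, sexes = sexes, rate = rate),
            class = "rs_ratetable")
}

#' @export
print.rs_ratetable <- function(x, ...) {
  cat("Population rate table (rs_ratetable)\n")
  cat("  ages :", min(x$ages), "-", max(x$ages), "\n")
  cat("  years:", min(x$years), "-", max(x$years), "\n")
  cat("  sexes:", paste(x$sexes, collapse = ", "), "\n")
  cat("  rate range:", format(range(x$rate), digits = 4), "per person-year\n")
  invisible(x)
}

#' Synthetic Gompertz-style rate table
#'
#' Builds a rate table with rates
#' `a * exp(b * age) * m(sex) * drift^(year - year0)`, capped at `max_rate`.
#' The sex multiplier is 1 for the first sex and `1/sex_ratio` for the second,
#' so `sex_ratio` is the first-to-second sex mortality rate ratio.  The default
#' slope approximates elderly male all-cause mortality in a high-income
#' country.
#'
#' @param a baseline rate at age 0 (per person-year), must be positive.
#' @param b log-linear slope per year of age (Gompertz shape), non-negative.
#' @param sex_ratio mortality rate ratio of the first sex to the second.
#' @param years calendar year grid.
#' @param drift per-calendar-year multiplicative trend.
#' @param ages age grid.
#' @param sexes sex labels; the first label carries multiplier 1.
#' @param year0 reference year for the drift term (default: first year).
#' @param max_rate cap applied to every cell (default 1 death per person-year).
#' @return An `rs_ratetable`.
#' @export
synthetic_ratetable <- function(a = 5e-5, b = 0.087, sex_ratio = 1,
                                years = 2009, drift = 1, ages = 0:109,
                                sexes = c("male", "female"), year0 = min(years),
                                max_rate = 1) {
  if (!is.numeric(a) || a <= 0) stop("`a` must be positive")
  if (b < 0) stop("`b` must be non-negative")
  if (sex_ratio <= 0) stop("`sex_ratio` must be positive")
  mult <- c(1, 1 / sex_ratio)[seq_along(sexes)]
  r <- outer(a * exp(b * ages), drift^(years - year0))
  rate <- array(0, dim = c(length(ages), length(years), length(sexes)))
  for (s in seq_along(sexes)) rate[, , s] <- pmin(r * mult[s], max_rate)
  rate_table(rate, ages, years, sexes)
}

#' Read a popmort-style rate table
#'
#' Long-format delimited text with header columns `sex`, `year`, `age` and
#' either `rate` (deaths per person-year) or `prob` (annual survival
#' probability, converted through `rate = -log(prob)`).  The dialect is an
#' explicit flag and never auto-detected, since silently misreading an annual
#' survival probability as a rate is a classic relative-survival bug.
#'
#' @param path file path.
#' @param dialect `"rate"` or `"prob"`.
#' @param sep field separator (default comma).
#' @return An `rs_ratetable`.
#' @export
read_ratetable <- function(path, dialect = c("rate", "prob"), sep = ",") {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sex", "year", "age", dialect)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("rate table file is missing column(s): ", paste(miss, collapse = ", "))
  val <- df[[dialect]]
  if (!is.numeric(val) || !is.numeric(df$year) || !is.numeric(df$age))
    stop("columns age, year and ", dialect, " must be numeric")
  if (dialect == "prob") {
    if (any(val <= 0 | val > 1))
      stop("annual survival probabilities must lie in (0, 1]")
    val <- -log(val)
  }
  ages <- seq(min(df$age), max(df$age))
  years <- seq(min(df$year), max(df$year))
  sexes <- sort(unique(as.character(df$sex)))
  full <- expand.grid(age = ages, year = years, sex = sexes,
                      stringsAsFactors = FALSE)
  key <- function(a, y, s) paste(a, y, s, sep = "|")
  got <- key(df$age, df$year, as.character(df$sex))
  if (anyDuplicated(got)) stop("duplicate (age, year, sex) cells in file")
  idx <- match(key(full$age, full$year, full$sex), got)
  if (anyNA(idx)) {
    bad <- full[is.na(idx), , drop = FALSE]
    show <- utils::head(sprintf("(age=%d, year=%d, sex=%s)",
                                bad$age, bad$year, bad$sex), 5L)
    stop("rate table has gaps; missing cells include: ",
         paste(show, collapse = ", "),
         if (nrow(bad) > 5L) sprintf(" and %d more", nrow(bad) - 5L) else "")
  }
  rate_table(val[idx], ages, years, sexes)
}

#' Write a rate table as popmort-style delimited text
#'
#' @param table an `rs_ratetable`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_ratetable <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "rs_ratetable"))
  full <- expand.grid(age = table$ages, year = table$years, sex = table$sexes,
                      stringsAsFactors = FALSE)
  full$rate <- as.vector(table$rate)
  full <- full[c("sex", "year", "age", "rate")]
  utils::write.table(full, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.check_sex <- function(table, sex) {
  bad <- setdiff(unique(as.character(sex)), table$sexes)
  if (length(bad))
    stop("sex level(s) not present in the rate table: ",
         paste(bad, collapse = ", "))
}

## Piecewise-constant hazard schedule for one subject.  Rates are constant
## within 1-year age x calendar-year bands; breakpoints occur wherever the
## attained age floor(age_dx + t) or attained year floor(year_dx + t) crosses
## an integer.  Ages/years beyond the grid are clamped to the nearest edge.
.sched <- function(table, age_dx, year_dx, sex, horizon) {
  si <- match(as.character(sex), table$sexes)
  cross <- function(x) {
    f <- ceiling(x) - x
    if (f == 0) f <- 1
    if (f > horizon) return(numeric(0))
    seq(f, horizon, by = 1)
  }
  br <- sort(unique(c(0, cross(age_dx), cross(year_dx), horizon)))
  br <- br[br <= horizon]
  if (br[length(br)] < horizon) br <- c(br, horizon)
  mid <- (br[-1] + br[-length(br)]) / 2
  ai <- pmin.int(pmax.int(floor(age_dx + mid) - table$ages[1] + 1L, 1L),
                 length(table$ages))
  yi <- pmin.int(pmax.int(floor(year_dx + mid) - table$years[1] + 1L, 1L),
                 length(table$years))
  rates <- table$rate[cbind(ai, yi, si)]
  list(breaks = br, rates = rates,
       cumhaz = c(0, cumsum(rates * diff(br))))
}

.sched_cumhaz <- function(sch, t) {
  i <- findInterval(t, sch$breaks, all.inside = TRUE)
  sch$cumhaz[i] + sch$rates[i] * (t - sch$breaks[i])
}

.sched_hazard <- function(sch, t) {
  n <- length(sch$breaks)
  i <- findInterval(t, sch$breaks)           # [b_i, b_{i+1}): right-continuous
  sch$rates[pmin.int(pmax.int(i, 1L), n - 1L)]
}

## Invert the cumulative expected hazard: smallest t with H(t) = target.
## Returns Inf when the schedule's total cumulated hazard never reaches target.
.sched_invert <- function(sch, target) {
  H <- sch$cumhaz
  if (target > H[length(H)]) return(Inf)
  i <- findInterval(target, H, all.inside = TRUE)
  if (sch$rates[i] <= 0) return(sch$breaks[i + 1])
  sch$breaks[i] + (target - H[i]) / sch$rates[i]
}

.demo_check <- function(table, age_dx, year_dx, sex, t) {
  .check_sex(table, sex)
  if (length(age_dx) != 1L || !is.finite(age_dx) || age_dx < 0)
    stop("`age_dx` must be a single finite non-negative number")
  if (!is.finite(year_dx)) stop("`year_dx` must be finite")
  if (any(is.na(t))) stop("`t` must not contain NA/NaN")
  if (any(t < 0)) stop("`t` must be non-negative")
  maxt <- if (length(t)) max(t) else 0
  h <- max(maxt, 1) + 1
  clamp <- (floor(age_dx + maxt) > max(table$ages)) ||
    (floor(age_dx) < min(table$ages)) ||
    (floor(year_dx + maxt) > max(table$years)) ||
    (floor(year_dx) < min(table$years))
  if (clamp)
    warning("attained age/year outside the rate table grid; clamped to the edge",
            call. = FALSE)
  h
}

#' Expected mortality rate for one subject
#'
#' Looks up the population rate at attained age `floor(age_dx + t)` and
#' attained calendar year `floor(year_dx + t)`, clamped to the grid bounds
#' (with a warning).  Piecewise constant in `t`.
#'
#' @param table an `rs_ratetable`.
#' @param age_dx age at diagnosis in years.
#' @param year_dx calendar year of diagnosis (may be fractional).
#' @param sex sex label, must exist in the table.
#' @param t time(s) since diagnosis, years.
#' @return Numeric vector of rates per person-year, one per element of `t`.
#' @export
expected_hazard <- function(table, age_dx, year_dx, sex, t) {
  h <- .demo_check(table, age_dx, year_dx, sex, t)
  sch <- .sched(table, age_dx, year_dx, sex, h)
  .sched_hazard(sch, t)
}

#' Expected cumulative hazard for one subject
#'
#' Exact integral of [expected_hazard()] over `(0, t]`: the integrand is
#' constant between attained-age/attained-year integer crossings, so the
#' integration is exact (no quadrature error).
#'
#' @inheritParams expected_hazard
#' @return Numeric vector of cumulative hazards.
#' @export
expected_cumhaz <- function(table, age_dx, year_dx, sex, t) {
  h <- .demo_check(table, age_dx, year_dx, sex, t)
  sch <- .sched(table, age_dx, year_dx, sex, h)
  .sched_cumhaz(sch, t)
}

#' Expected survival \eqn{S^*(t)} for one subject
#'
#' @inheritParams expected_hazard
#' @return `exp(-expected_cumhaz(...))`, in (0, 1].
#' @export
expected_survival <- function(table, age_dx, year_dx, sex, t) {
  exp(-expected_cumhaz(table, age_dx, year_dx, sex, t))
}

#' Inverse-expected-survival weight \eqn{w^*(t) = 1/S^*(t)}
#'
#' The time-dependent weight that compensates the selective depletion of
#' subjects with high other-cause mortality; always at least 1 and
#' non-decreasing in `t`.
#'
#' @inheritParams expected_hazard
#' @return Numeric vector of weights.
#' @export
expected_weight <- function(table, age_dx, year_dx, sex, t) {
  exp(expected_cumhaz(table, age_dx, year_dx, sex, t))
}
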