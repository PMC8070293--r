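#' Cohort of individual survival records
#'
#' Validates a data frame of individual-level survival data for relative
#' survival analysis.  Required columns: `id`, `time` (follow-up in years,
#' positive), `dead` (all-cause death indicator, 0/1), `age_dx` (age at
#' diagnosis), `sex`, `year_dx` (calendar year of diagnosis).  Optional:
#' `group` (comparison covariate, coerced to factor) and `w_a` (positive
#' standardization weight, default 1).
#'
#' @param data a data frame.
#' @return The validated data frame with class `rs_cohort` prepended.
#' @export
as_cohort <- function(data) {
  need <- c("id", "time", "dead", "age_dx", "sex", "year_dx")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  if (anyDuplicated(data$id)) stop("`id` must be unique")
  if (!is.numeric(data$time) || any(!is.finite(data$time)) ||
      any(data$time <= 0))
    stop("`time` must be finite and > 0")
  if (!all(data$dead %in% c(0, 1))) stop("`dead` must be 0 or 1")
  if (!is.numeric(data$age_dx) || any(!is.finite(data$age_dx)) ||
      any(data$age_dx < 0))
    stop("`age_dx` must be finite and non-negative")
  if (!is.numeric(data$year_dx) || any(!is.finite(data$year_dx)))
    stop("`year_dx` must be finite")
  if (is.null(data$w_a)) data$w_a <- 1
  if (any(!is.finite(data$w_a)) || any(data$w_a <= 0))
    stop("`w_a` must be finite and positive")
  if (!is.null(data$group)) data$group <- factor(data$group)
  class(data) <- unique(c("rs_cohort", class(data)))
  data
}

#' Read a cohort from delimited text
#'
#' Strict header: `id`, `time`, `dead`, `age_dx`, `sex`, `year_dx`, optional
#' `group` and `w_a`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return An `rs_cohort` data frame.
#' @export
read_cohort <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_cohort(df)
}

#' Reference age distribution for external standardization
#'
#' @param breaks increasing numeric vector of age-group boundaries; group `g`
#'   is `[breaks[g], breaks[g+1])`.  Use `Inf` for an open last group.
#' @param props non-negative proportions per group, summing to 1.
#' @return An object of class `rs_refdist`.
#' @export
ref_dist <- function(breaks, props) {
  if (length(props) != length(breaks) - 1L)
    stop("`props` must have one entry per age group")
  if (any(diff(breaks) <= 0)) stop("`breaks` must be strictly increasing")
  if (any(props < 0)) stop("`props` must be non-negative")
  if (abs(sum(props) - 1) > 1e-8) stop("`props` must sum to 1")
  structure(list(breaks = breaks, props = props,
                 labels = paste0("[", utils::head(breaks, -1L), ",",
                                 breaks[-1L], ")")),
            class = "rs_refdist")
}

.ref_group <- function(ref, age) {
  g <- findInterval(age, ref$breaks, rightmost.closed = FALSE)
  if (any(g < 1L | g > length(ref$props)))
    stop("some ages fall outside the reference age-group boundaries")
  g
}

#' Standardization weights \eqn{w^a_i = p^R_i / p^a_i}
#'
#' The ratio of the reference proportion of the subject's age group to the
#' observed proportion.  When comparison groups are modelled the observed
#' proportions must be computed separately within each group, so that every
#' group is standardized to the same reference distribution; pass the group
#' variable through `by`.
#'
#' @param cohort an `rs_cohort`.
#' @param ref an [ref_dist()] object.
#' @param by optional name of a cohort column (or a vector) defining the
#'   standardization strata; default: the whole cohort is one stratum.
#' @return Numeric vector of weights, one per subject.
#' @export
standardization_weights <- function(cohort, ref, by = NULL) {
  stopifnot(inherits(ref, "rs_refdist"))
  g <- .ref_group(ref, cohort$age_dx)
  strat <- if (is.null(by)) rep(1L, nrow(cohort))
           else if (is.character(by) && length(by) == 1L) cohort[[by]]
           else by
  w <- numeric(nrow(cohort))
  for (s in unique(strat)) {
    sel <- which(strat == s)
    obs <- tabulate(g[sel], nbins = length(ref$props)) / length(sel)
    empty <- which(obs == 0 & ref$props > 0)
    if (length(empty))
      stop("reference group(s) ", paste(ref$labels[empty], collapse = ", "),
           " have positive weight but no observed subjects in stratum ", s)
    w[sel] <- ref$props[g[sel]] / obs[g[sel]]
  }
  w
}

#' Split follow-up into intervals
#'
#' Expands each subject into person-time intervals cut at multiples of
#' `width` (or at user-supplied `cuts`), intersected with `(0, t_i]`.  The
#' final, possibly partial, interval ends exactly at `t_i` and carries the
#' event flag for subjects who died.
#'
#' @param cohort an `rs_cohort`.
#' @param width interval width in years (positive); ignored when `cuts` given.
#' @param cuts optional increasing vector of cut points.
#' @return Data frame with columns `id`, `k` (interval index), `start`,
#'   `stop`, `mid` (interval midpoint) and `event`.
#' @export
split_time <- function(cohort, width = 0.2, cuts = NULL) {
  if (is.null(cuts)) {
    if (!is.numeric(width) || width <= 0) stop("`width` must be positive")
    cuts <- seq(width, max(cohort$time) + width, by = width)
  } else {
    cuts <- sort(unique(cuts[cuts > 0]))
  }
  t_i <- cohort$time
  nint <- findInterval(t_i, cuts, left.open = TRUE) + 1L  # cuts strictly below t_i
  idx <- rep.int(seq_along(t_i), nint)
  k <- sequence(nint)
  stop_ <- pmin(cuts[k], t_i[idx])
  # guard against stop == start from floating-point ties at t_i
  start_ <- c(0, cuts)[k]
  keep <- stop_ > start_
  idx <- idx[keep]; k <- k[keep]; stop_ <- stop_[keep]; start_ <- start_[keep]
  last <- c(idx[-1] != idx[-length(idx)], TRUE)
  data.frame(id = cohort$id[idx], k = k, start = start_, stop = stop_,
             mid = (start_ + stop_) / 2,
             event = as.integer(last & cohort$dead[idx] == 1))
}

## Per-subject hazard schedules for a whole cohort (internal).
.cohort_scheds <- function(cohort, table, horizon = NULL) {
  .check_sex(table, cohort$sex)
  if (is.null(horizon)) horizon <- max(cohort$time) + 1
  lapply(seq_len(nrow(cohort)), function(i)
    .sched(table, cohort$age_dx[i], cohort$year_dx[i],
           cohort$sex[i], max(horizon, cohort$time[i] + 1)))
}

## Matrices of S*^{-1}-weights and expected hazards at a set of times
## (internal).  Returns W (weight w_a * exp(H*)) and HZ (expected rate), both
## length(times) x n, plus the at-risk mask  t_j >= time.
.weights_at <- function(cohort, scheds, times, w_a = NULL) {
  n <- nrow(cohort)
  if (is.null(w_a)) w_a <- cohort$w_a
  W <- HZ <- matrix(0, length(times), n)
  for (j in seq_len(n)) {
    W[, j] <- w_a[j] * exp(.sched_cumhaz(scheds[[j]], times))
    HZ[, j] <- .sched_hazard(scheds[[j]], times)
  }
  Y <- outer(times, cohort$time, `<=`)
  list(W = W, HZ = HZ, Y = Y)
}

## Chunked risk-set sums at a vector of times (internal): den = sum_j w_j(t)
## Y_j(t), num = sum_j w_j(t) h*_j(t) Y_j(t), and (for estimators) the event
## sums jn = sum_{deaths at t} w_j(t), js = sum w_j(t)^2.  Chunking bounds
## memory at ~`chunk_cells` doubles regardless of cohort size.
.riskset_sums <- function(cohort, scheds, times, w_a = NULL,
                          jumps = TRUE, chunk_cells = 4e6) {
  n <- nrow(cohort)
  L <- length(times)
  den <- num <- jn <- js <- numeric(L)
  blk <- max(1L, floor(chunk_cells / max(n, 1L)))
  for (s0 in seq(1, L, by = blk)) {
    ix <- s0:min(s0 + blk - 1L, L)
    wa <- .weights_at(cohort, scheds, times[ix], w_a)
    den[ix] <- rowSums(wa$W * wa$Y)
    num[ix] <- rowSums(wa$W * wa$HZ * wa$Y)
    if (jumps) {
      dN <- outer(times[ix], cohort$time, `==`) &
        matrix(cohort$dead == 1, length(ix), n, byrow = TRUE)
      jn[ix] <- rowSums(wa$W * dN)
      js[ix] <- rowSums(wa$W^2 * dN)
    }
  }
  list(den = den, num = num, jn = jn, js = js)
}

#' Weighted mean expected mortality rate at event times
#'
#' \deqn{\bar h^*(t) = \frac{\sum_{j \in R(t)} w_j(t)\, h^*(t|X_j)}
#'                          {\sum_{j \in R(t)} w_j(t)}}
#' with combined weights \eqn{w_j(t) = w^a_j / S^*_j(t)} and risk set
#' \eqn{R(t) = \{j : t_j \ge t\}} (subjects censored exactly at `t` are still
#' at risk).  When comparison groups are modelled this must be computed
#' separately within each group; pass the subgroup as `subset`.
#'
#' @param cohort an `rs_cohort`.
#' @param table an `rs_ratetable`.
#' @param times event time(s) at which to evaluate.
#' @param w_a optional standardization weights (default: cohort `w_a`).
#' @param subset optional logical/integer subset of subjects forming the risk
#'   population (e.g. one comparison group).
#' @return Numeric vector, one weighted mean rate per time.
#' @export
mean_expected_hazard <- function(cohort, table, times, w_a = NULL,
                                 subset = NULL) {
  if (!is.null(subset)) {
    cohort <- cohort[subset, , drop = FALSE]
    if (!is.null(w_a)) w_a <- w_a[subset]
  }
  sch <- .cohort_scheds(cohort, table, horizon = max(times) + 1)
  rs <- .riskset_sums(cohort, sch, times, w_a)
  if (any(rs$den == 0)) stop("empty risk set at time(s) ",
                             paste(times[rs$den == 0], collapse = ", "))
  rs$num / rs$den
}
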