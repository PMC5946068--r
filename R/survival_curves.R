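#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, computed with
#' [survival::survfit()]. With no censoring it equals the empirical
#' survival function.
#'
#' @param time ages at death or censoring (years).
#' @param event 1 = death, 0 = right-censored (default all deaths).
#' @return Object of class `km_curve` with `time`, `surv`, `n_risk`,
#'   `n_event`, `lower`, `upper` (95% log-log CI).
#' @export
km_estimate <- function(time, event = NULL) {
  time <- as.numeric(time)
  if (is.null(event)) event <- rep(1, length(time))
  stopifnot(length(event) == length(time), all(time >= 0))
  if (sum(event) == 0) stop("no events: cannot estimate survival")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "log-log")
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, lower = sf$lower, upper = sf$upper,
                 n = length(time)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary ages
#'
#' Right-continuous step-function evaluation; S(age) = 1 before the first
#' event time.
#'
#' @param curve a [km_estimate()] result.
#' @param age ages (years).
#' @return Survival probabilities.
#' @export
km_survival <- function(curve, age) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- findInterval(age, curve$time)
  c(1, curve$surv)[idx + 1]
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", sum(x$n_event),
      ", median =", signif(x$time[which(x$surv <= 0.5)[1]], 4), "years\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = "age (years)", ylab = "S(age)", ylim = c(0, 1), ...)
  invisible(x)
}

epanechnikov <- function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)

# integral of the Epanechnikov kernel over (-Inf, u]
epanechnikov_cdf <- function(u) {
  u <- pmin(pmax(u, -1), 1)
  0.5 + 0.75 * (u - u^3 / 3)
}

#' Kernel-smoothed hazard curve
#'
#' Smooths the Nelson-Aalen hazard increments \eqn{dN(t_i)/Y(t_i)} with an
#' Epanechnikov kernel, with boundary correction by renormalizing each
#' kernel to unit mass inside the observation window. Under this
#' normalization the curve integrates (over the window) to the total
#' cumulative hazard regardless of bandwidth.
#'
#' @inheritParams km_estimate
#' @param bandwidth kernel half-width in years; default one tenth of the
#'   death-age range.
#' @param grid ages at which to evaluate; default 101 points spanning the
#'   observed ages.
#' @return Object of class `hazard_curve` with `grid`, `hazard`,
#'   `bandwidth`.
#' @export
smoothed_hazard <- function(time, event = NULL, bandwidth = NULL,
                            grid = NULL) {
  time <- as.numeric(time)
  if (is.null(event)) event <- rep(1, length(time))
  stopifnot(length(event) == length(time), all(time >= 0))
  if (sum(event) == 0) stop("no events: cannot estimate a hazard")
  dtimes <- time[event == 1]
  if (is.null(bandwidth)) bandwidth <- max(diff(range(dtimes)) / 10, 1e-6)
  stopifnot(bandwidth > 0)
  if (is.null(grid)) grid <- seq(min(time), max(time), length.out = 101)
  if (length(grid) == 0) stop("empty evaluation grid")
  lo <- min(time); hi <- max(time)
  # Nelson-Aalen increments at the distinct event times
  ord <- order(time)
  ts <- time[ord]; ev <- event[ord]
  ut <- unique(ts[ev == 1])
  n_at_risk <- vapply(ut, function(t) sum(ts >= t), numeric(1))
  d <- vapply(ut, function(t) sum(ts == t & ev == 1), numeric(1))
  incr <- d / n_at_risk
  # boundary-corrected kernel mass inside [lo, hi] for each event time
  mass <- epanechnikov_cdf((hi - ut) / bandwidth) -
    epanechnikov_cdf((lo - ut) / bandwidth)
  haz <- vapply(grid, function(g) {
    sum(epanechnikov((g - ut) / bandwidth) / bandwidth * incr / mass)
  }, numeric(1))
  structure(list(grid = grid, hazard = haz, bandwidth = bandwidth,
                 cumhaz_total = sum(incr)),
            class = "hazard_curve")
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat("Smoothed hazard curve on", length(x$grid), "grid points, bandwidth",
      signif(x$bandwidth, 4), "years\n")
  invisible(x)
}

#' @export
plot.hazard_curve <- function(x, log = "", ...) {
  graphics::plot(x$grid, x$hazard, type = "l", log = log,
                 xlab = "age (years)", ylab = "hazard (per year)", ...)
  invisible(x)
}

# Breslow partial log-likelihood for a single binary covariate,
# and its first two derivatives in the log hazard ratio b
breslow_pll <- function(b, time, event, group) {
  ord <- order(time)
  t <- time[ord]; e <- event[ord]; x <- group[ord]
  ut <- unique(t[e == 1])
  ll <- 0; score <- 0; info <- 0
  for (tt in ut) {
    risk <- t >= tt
    dead <- t == tt & e == 1
    d <- sum(dead)
    s1 <- sum(x[dead])
    w <- exp(b * x[risk])
    S0 <- sum(w)
    S1 <- sum(w * x[risk])
    S2 <- sum(w * x[risk]^2)
    ll <- ll + b * s1 - d * log(S0)
    score <- score + s1 - d * S1 / S0
    info <- info + d * (S2 / S0 - (S1 / S0)^2)
  }
  list(ll = ll, score = score, info = info)
}

#' Two-group proportional-hazards contrast
#'
#' Log hazard ratio of group 1 versus group 0 from a one-covariate Cox
#' partial likelihood with Breslow tie handling, maximized by
#' Newton-Raphson, with a Wald test. The estimate depends on the data only
#' through ranks, so it is invariant under strictly monotone transforms of
#' the time axis.
#'
#' @inheritParams km_estimate
#' @param group binary group indicator (0/1 or a two-level factor).
#' @return Object of class `hazard_ratio_test`: `log_hr`, `se`, `z`,
#'   `p_value`, `hr`.
#' @export
two_group_hazard_ratio <- function(time, event = NULL, group) {
  time <- as.numeric(time)
  if (is.null(event)) event <- rep(1, length(time))
  if (is.factor(group) || is.character(group))
    group <- as.integer(factor(group)) - 1L
  group <- as.numeric(group)
  stopifnot(length(event) == length(time), length(group) == length(time),
            all(group %in% c(0, 1)))
  for (g in c(0, 1))
    if (sum(event[group == g]) == 0)
      stop("group ", g, " has no events")
  b <- 0
  for (it in 1:50) {
    pl <- breslow_pll(b, time, event, group)
    if (pl$info <= 0) break
    step <- pl$score / pl$info
    b <- b + step
    if (abs(step) < 1e-10) break
  }
  pl <- breslow_pll(b, time, event, group)
  se <- 1 / sqrt(pl$info)
  z <- b / se
  structure(list(log_hr = b, hr = exp(b), se = se, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 logLik = pl$ll),
            class = "hazard_ratio_test")
}

#' @export
print.hazard_ratio_test <- function(x, digits = 4, ...) {
  cat("Two-group proportional-hazards contrast (Breslow ties)\n")
  cat("  log HR =", signif(x$log_hr, digits), " (HR =",
      signif(x$hr, digits), "), se =", signif(x$se, digits), "\n")
  cat("  Wald z =", signif(x$z, digits), ", p =",
      format.pval(x$p_value, digits = digits), "\n")
  invisible(x)
}
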