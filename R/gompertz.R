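# Gompertz mortality model: hazard mu(x) = alpha * exp(beta * x).
# beta, the slope of log-hazard against age, is the demographic rate of
# aging; the model degenerates to the exponential as beta -> 0, and all
# formulas below take that limit stably.

#' Gompertz hazard, cumulative hazard and survival
#'
#' The Gompertz mortality model has hazard
#' \eqn{\mu(x) = \alpha e^{\beta x}}, cumulative hazard
#' \eqn{H(x) = (\alpha/\beta)(e^{\beta x} - 1)} and survival
#' \eqn{S(x) = \exp(-H(x))}. All three are evaluated stably as
#' \eqn{\beta \to 0} (the exponential limit).
#'
#' @param age non-negative age(s) in years.
#' @param alpha baseline hazard at age 0 (per year, > 0).
#' @param beta exponential slope of the hazard (per year); the "rate of
#'   aging". May be negative or zero.
#' @return Numeric vector.
#' @export
gompertz_hazard <- function(age, alpha, beta) {
  stopifnot(alpha > 0)
  alpha * exp(beta * age)
}

#' @rdname gompertz_hazard
#' @export
gompertz_cumhaz <- function(age, alpha, beta) {
  stopifnot(alpha > 0, all(age >= 0))
  if (abs(beta) < 1e-10) {
    # second-order expansion of (exp(b x) - 1) / b around b = 0
    alpha * age * (1 + beta * age / 2 + (beta * age)^2 / 6)
  } else {
    alpha * expm1(beta * age) / beta
  }
}

#' @rdname gompertz_hazard
#' @export
gompertz_survival <- function(age, alpha, beta) {
  exp(-gompertz_cumhaz(age, alpha, beta))
}

#' Draw Gompertz lifespans by inverse-CDF sampling
#'
#' Inverts \eqn{S(x) = u}: \eqn{x = \beta^{-1}\log(1 - (\beta/\alpha)\log u)}
#' with the exponential fallback \eqn{x = -\log(u)/\alpha} when
#' \eqn{|\beta|} is numerically zero.
#'
#' @inheritParams gompertz_hazard
#' @param n number of draws.
#' @return Vector of `n` non-negative lifespans (years).
#' @export
rgompertz <- function(n, alpha, beta) {
  stopifnot(n >= 1, alpha > 0)
  u <- stats::runif(n)
  if (abs(beta) < 1e-10) {
    -log(u) / alpha
  } else {
    log1p(-(beta / alpha) * log(u)) / beta
  }
}

#' Solve the Gompertz baseline hazard for a target median lifespan
#'
#' Given the slope `beta`, returns the `alpha` for which the median of the
#' Gompertz lifespan distribution equals `median_age`.
#'
#' @param beta Gompertz slope (per year).
#' @param median_age target median lifespan (years, > 0).
#' @return `alpha` (per year).
#' @export
gompertz_alpha_for_median <- function(beta, median_age) {
  stopifnot(median_age > 0)
  if (abs(beta) < 1e-10) return(log(2) / median_age)
  beta * log(2) / expm1(beta * median_age)
}

# negative log-likelihood on par = (log alpha, beta)
gompertz_negll <- function(par, time, event, ilo, ihi) {
  alpha <- exp(par[1])
  beta <- par[2]
  if (!is.finite(alpha) || alpha <= 0) return(1e300)
  ll <- 0
  if (length(time)) {
    H <- gompertz_cumhaz(time, alpha, beta)
    ll <- ll + sum(event * (par[1] + beta * time)) - sum(H)
  }
  if (length(ilo)) {
    Slo <- gompertz_survival(ilo, alpha, beta)
    Shi <- ifelse(is.finite(ihi), gompertz_survival(ihi, alpha, beta), 0)
    p <- pmax(Slo - Shi, 1e-300)
    ll <- ll + sum(log(p))
  }
  if (!is.finite(ll)) return(1e300)
  -ll
}

# crude life-table slope for initial values: log occurrence/exposure hazard
# over death-age deciles, least-squares line through the positive entries
gompertz_init <- function(ages) {
  ages <- ages[is.finite(ages)]
  if (length(ages) < 10 || stats::sd(ages) == 0)
    return(c(log(1 / max(mean(ages), 1e-6)), 0.05))
  br <- unique(stats::quantile(ages, probs = seq(0, 1, length.out = 11),
                               names = FALSE))
  if (length(br) < 3) return(c(log(1 / mean(ages)), 0.05))
  br[1] <- br[1] - 1e-9
  bin <- cut(ages, br)
  d <- tabulate(bin, nbins = length(br) - 1)
  # person-years contributed to each bin by the sorted sample
  expo <- vapply(seq_len(length(br) - 1), function(i) {
    lo <- br[i]; hi <- br[i + 1]
    sum(pmax(pmin(ages, hi) - lo, 0))
  }, numeric(1))
  mid <- (br[-1] + br[-length(br)]) / 2
  ok <- d > 0 & expo > 0
  if (sum(ok) < 2) return(c(log(1 / mean(ages)), 0.05))
  fit <- stats::lm.fit(cbind(1, mid[ok]), log(d[ok] / expo[ok]))
  cf <- fit$coefficients
  if (!all(is.finite(cf))) cf <- c(log(1 / mean(ages)), 0.05)
  unname(cf)
}

#' Fit the Gompertz mortality model by maximum likelihood
#'
#' Fits \eqn{\mu(x) = \alpha e^{\beta x}} to lifespans recorded either
#' exactly (with optional right censoring) or as age intervals (binned
#' ages), by direct maximization of the log-likelihood over
#' \eqn{(\log\alpha, \beta)} with a quasi-Newton method, initialized from a
#' least-squares line through the log life-table hazard. Interval
#' contributions are \eqn{P(\mathrm{death} \in [lo, hi))
#' = S(lo) - S(hi)}. The slope is not constrained positive.
#'
#' @param time ages at death or censoring (years), exact mode.
#' @param event 1 = death, 0 = right-censored (default all deaths).
#' @param lower,upper interval mode: vectors of bin bounds `[lower, upper)`
#'   in years; `upper = Inf` (or `NA`) for an open-ended top bin. Supply
#'   either `time` or `lower`/`upper` (mixing is allowed; interval rows are
#'   treated as deaths within their bin).
#' @param control passed to [stats::optim()] (method `"BFGS"`).
#' @return Object of class `gompertz_fit` with components `alpha`, `beta`,
#'   `logLik`, `vcov` (for `(log alpha, beta)`), `n`, `mode`.
#' @examples
#' set.seed(1)
#' x <- rgompertz(2000, alpha = 5e-5, beta = 0.09)
#' fit <- fit_gompertz(x)
#' coef(fit)
#' @export
fit_gompertz <- function(time = NULL, event = NULL, lower = NULL,
                         upper = NULL, control = list()) {
  has_exact <- !is.null(time) && length(time) > 0
  has_int <- !is.null(lower) && length(lower) > 0
  if (!has_exact && !has_int) stop("no data supplied")
  if (has_exact) {
    time <- as.numeric(time)
    if (is.null(event)) event <- rep(1, length(time))
    event <- as.numeric(event)
    stopifnot(length(event) == length(time), all(time >= 0))
    if (sum(event) > 0 &&
        length(unique(time[event == 1])) < 2 && !has_int)
      stop("need at least 2 distinct death ages")
  } else {
    time <- numeric(0); event <- numeric(0)
  }
  if (has_int) {
    lower <- as.numeric(lower)
    upper <- as.numeric(upper)
    upper[is.na(upper)] <- Inf
    stopifnot(length(upper) == length(lower), all(lower >= 0),
              all(upper > lower))
    if (!has_exact && length(unique(lower)) < 2)
      stop("need at least 2 occupied bins")
  } else {
    lower <- numeric(0); upper <- numeric(0)
  }
  init_ages <- c(time[event == 1],
                 if (has_int) ifelse(is.finite(upper),
                                     (lower + upper) / 2, lower + 1))
  par0 <- gompertz_init(init_ages)
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
  opt <- stats::optim(par0, gompertz_negll, time = time, event = event,
                      ilo = lower, ihi = upper,
                      method = "BFGS", control = ctrl, hessian = TRUE)
  if (opt$convergence != 0)
    stop("Gompertz MLE did not converge (code ", opt$convergence,
         "); last iterate log(alpha)=", signif(opt$par[1], 6),
         ", beta=", signif(opt$par[2], 6))
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  dimnames(vc) <- list(c("log_alpha", "beta"), c("log_alpha", "beta"))
  structure(list(alpha = exp(opt$par[1]), beta = opt$par[2],
                 log_alpha = opt$par[1], logLik = -opt$value, vcov = vc,
                 n = length(time) + length(lower),
                 mode = if (has_int && !has_exact) "interval"
                        else if (has_exact && !has_int) "exact" else "mixed"),
            class = "gompertz_fit")
}

#' @export
coef.gompertz_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
logLik.gompertz_fit <- function(object, ...) {
  structure(object$logLik, df = 2, nobs = object$n, class = "logLik")
}

#' @export
print.gompertz_fit <- function(x, digits = 4, ...) {
  cat("Gompertz mortality fit (", x$mode, " ages, n = ", x$n, ")\n",
      sep = "")
  cat("  alpha (baseline hazard):", signif(x$alpha, digits), "per year\n")
  cat("  beta  (rate of aging):  ", signif(x$beta, digits), "per year\n")
  cat("  log-likelihood:", format(x$logLik, digits = digits + 3), "\n")
  invisible(x)
}

#' @export
summary.gompertz_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  est <- c(object$log_alpha, object$beta)
  tab <- cbind(estimate = est, se = se, z = est / se,
               p = 2 * stats::pnorm(-abs(est / se)))
  rownames(tab) <- c("log_alpha", "beta")
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.gompertz_fit"
  out
}

#' @export
print.summary.gompertz_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (log-alpha scale):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
predict.gompertz_fit <- function(object, age,
                                 type = c("survival", "hazard", "cumhaz"),
                                 ...) {
  type <- match.arg(type)
  switch(type,
         survival = gompertz_survival(age, object$alpha, object$beta),
         hazard = gompertz_hazard(age, object$alpha, object$beta),
         cumhaz = gompertz_cumhaz(age, object$alpha, object$beta))
}

#' @export
simulate.gompertz_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rgompertz(nsim, object$alpha, object$beta)
}

#' @export
plot.gompertz_fit <- function(x, ages = NULL, log = "y", ...) {
  if (is.null(ages)) {
    # plot out to the 1st-percentile survival age
    top <- if (abs(x$beta) < 1e-10) -log(0.01) / x$alpha
           else log1p(-(x$beta / x$alpha) * log(0.01)) / x$beta
    ages <- seq(0, top, length.out = 200)
  }
  graphics::plot(ages, predict(x, ages, type = "hazard"), type = "l",
                 log = log, xlab = "age (years)", ylab = "hazard (per year)",
                 ...)
  invisible(x)
}
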