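# Multinomial logistic age-trajectory model of cause-of-death proportions.
# For K causes the probability that a death at a given age is from cause g is
#   p_g(age) = softmax( a_g + sum_{i=1..4} b_{g,i} z^i ),
# a fourth-order polynomial in standardized age z = (age - center)/scale.
# Standardizing before the polynomial expansion keeps age^4 terms on a
# sane numeric scale (raw human ages ~100 would give 1e8); the model is a
# reparameterization of the same polynomial on raw age. One cause (the
# alphabetically first by default) is the reference with all parameters 0.

trajectory_design <- function(age, center, scale, degree) {
  z <- (age - center) / scale
  X <- outer(z, 0:degree, `^`)
  colnames(X) <- c("(Intercept)", paste0("z", seq_len(degree)))
  X
}

row_max0 <- function(eta) {
  # pmax over columns and 0, avoiding apply() overhead on big n
  m <- rep(0, nrow(eta))
  for (j in seq_len(ncol(eta))) m <- pmax(m, eta[, j])
  m
}

# log-sum-exp row-wise over cbind(0, eta)
softmax_prob <- function(eta) {
  # eta: n x (K-1) linear predictors of the non-reference causes
  ez <- exp(cbind(0, eta) - row_max0(eta))
  ez / rowSums(ez)
}

multinom_negll <- function(par, X, Yidx, K, ridge = 0) {
  P <- ncol(X)
  B <- matrix(par, nrow = P, ncol = K - 1)
  eta <- X %*% B
  m <- row_max0(eta)
  lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
  full <- cbind(0, eta)
  ll <- sum(full[cbind(seq_len(nrow(X)), Yidx)]) - sum(lse)
  -(ll - ridge * sum(par^2))
}

multinom_grad <- function(par, X, Yidx, K, ridge = 0) {
  P <- ncol(X)
  B <- matrix(par, nrow = P, ncol = K - 1)
  eta <- X %*% B
  Pr <- softmax_prob(eta)
  Yind <- matrix(0, nrow(X), K)
  Yind[cbind(seq_len(nrow(X)), Yidx)] <- 1
  G <- t(X) %*% (Yind[, -1, drop = FALSE] - Pr[, -1, drop = FALSE])
  -(as.vector(G) - 2 * ridge * par)
}

#' Fit a multinomial cause-of-death age-trajectory model
#'
#' Maximum-likelihood fit of the softmax model with a fourth-order
#' polynomial in standardized age for each non-reference cause. The
#' likelihood is concave once a reference cause is fixed, so the optimum is
#' unique; optimization is quasi-Newton (BFGS) with analytic gradient.
#' Causes with zero deaths are dropped with a warning. If the fit shows
#' signs of separation (unbounded coefficients), it is refit with a small
#' ridge penalty and a warning.
#'
#' @param age ages at death (years), one per death.
#' @param cause cause label per death (character or factor).
#' @param degree polynomial degree (default 4).
#' @param ref reference cause (default alphabetically first); its
#'   coefficients are fixed at 0.
#' @param start optional starting coefficient vector (internal use).
#' @return Object of class `cause_trajectory`: `labels`, `ref`,
#'   `coefficients` (K x (degree+1) matrix on the standardized-age scale;
#'   reference row all zero), `center`, `scale`, `degree`, `logLik`, `n`,
#'   and the data (`age`, `cause`) for bootstrap resampling.
#' @examples
#' set.seed(1)
#' age <- runif(500, 0, 15)
#' cause <- ifelse(runif(500) < 1 / (1 + exp(-(age - 8))), "neoplastic",
#'                 "traumatic")
#' fit <- fit_cause_trajectory(age, cause)
#' predict(fit, age = c(2, 8, 14))
#' @export
fit_cause_trajectory <- function(age, cause, degree = 4, ref = NULL,
                                 start = NULL) {
  age <- as.numeric(age)
  if (is.factor(cause) && any(table(cause) == 0))
    warning("dropping causes with zero deaths: ",
            paste(setdiff(levels(cause), unique(as.character(cause))),
                  collapse = ", "))
  cause <- as.character(cause)
  stopifnot(length(age) == length(cause), all(is.finite(age)))
  tab <- table(cause)
  labels <- sort(names(tab[tab > 0]))
  if (length(labels) < 2) stop("need at least 2 distinct causes")
  if (length(age) < 50)
    warning("fewer than 50 deaths; trajectory estimates will be unstable")
  if (is.null(ref)) ref <- labels[1]
  stopifnot(ref %in% labels)
  labels <- c(ref, setdiff(labels, ref))
  K <- length(labels)
  center <- mean(age)
  scale <- stats::sd(age)
  if (!is.finite(scale) || scale == 0) scale <- 1
  X <- trajectory_design(age, center, scale, degree)
  Yidx <- match(cause, labels)
  P <- ncol(X)
  par0 <- if (is.null(start)) rep(0, P * (K - 1)) else start
  fit_once <- function(ridge) {
    stats::optim(par0, multinom_negll, multinom_grad, X = X, Yidx = Yidx,
                 K = K, ridge = ridge, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-12))
  }
  opt <- fit_once(0)
  if (opt$convergence != 0 || max(abs(opt$par)) > 50) {
    warning("possible separation or non-convergence; refitting with a ",
            "small ridge penalty")
    opt <- fit_once(1e-4)
  }
  B <- rbind(0, t(matrix(opt$par, nrow = P, ncol = K - 1)))
  dimnames(B) <- list(labels, colnames(X))
  structure(list(labels = labels, ref = ref, coefficients = B,
                 center = center, scale = scale, degree = degree,
                 logLik = -opt$value, n = length(age),
                 convergence = opt$convergence,
                 age = age, cause = cause),
            class = "cause_trajectory")
}

#' Build a trajectory model directly from coefficients
#'
#' Constructs a `cause_trajectory` object from user-supplied coefficients
#' (on the standardized-age scale), for use as a simulation generator.
#'
#' @param coefficients K x (degree+1) matrix, rows named by cause; the first
#'   row is the reference and is forced to zero.
#' @param center,scale age standardization constants (years).
#' @return A `cause_trajectory`.
#' @export
trajectory_model <- function(coefficients, center, scale) {
  stopifnot(is.matrix(coefficients), !is.null(rownames(coefficients)),
            scale > 0)
  coefficients[1, ] <- 0
  structure(list(labels = rownames(coefficients),
                 ref = rownames(coefficients)[1],
                 coefficients = coefficients, center = center, scale = scale,
                 degree = ncol(coefficients) - 1L, logLik = NA_real_,
                 n = 0L, convergence = 0L, age = NULL, cause = NULL),
            class = "cause_trajectory")
}

#' Predicted cause-of-death proportions at given ages
#'
#' Evaluates the softmax model; each row is a probability vector over the
#' causes (non-negative, sums to 1).
#'
#' @param model a [fit_cause_trajectory()] or [trajectory_model()] object.
#' @param age ages (years).
#' @return Matrix `length(age)` x K with columns named by cause.
#' @export
predict_proportions <- function(model, age) {
  stopifnot(inherits(model, "cause_trajectory"))
  X <- trajectory_design(as.numeric(age), model$center, model$scale,
                         model$degree)
  eta <- X %*% t(model$coefficients[-1, , drop = FALSE])
  Pr <- softmax_prob(eta)
  colnames(Pr) <- model$labels
  Pr
}

#' @export
predict.cause_trajectory <- function(object, age, ...) {
  predict_proportions(object, age)
}

#' @export
coef.cause_trajectory <- function(object, ...) object$coefficients

#' @export
logLik.cause_trajectory <- function(object, ...) {
  structure(object$logLik,
            df = (length(object$labels) - 1) * (object$degree + 1),
            nobs = object$n, class = "logLik")
}

#' @export
print.cause_trajectory <- function(x, digits = 4, ...) {
  cat("Multinomial cause-of-death age-trajectory model\n")
  cat("  causes:", paste(x$labels, collapse = ", "), "\n")
  cat("  reference:", x$ref, "; polynomial degree:", x$degree, "\n")
  cat("  age standardization: center =", signif(x$center, digits),
      ", scale =", signif(x$scale, digits), "\n")
  if (x$n > 0)
    cat("  n =", x$n, ", log-likelihood =",
        format(x$logLik, digits = digits + 3), "\n")
  invisible(x)
}

#' @export
summary.cause_trajectory <- function(object, ...) {
  cat_tab <- table(factor(object$cause, levels = object$labels))
  out <- list(model = object, counts = cat_tab)
  class(out) <- "summary.cause_trajectory"
  out
}

#' @export
print.summary.cause_trajectory <- function(x, ...) {
  print(x$model)
  cat("\nDeaths per cause:\n")
  print(x$counts)
  cat("\nCoefficients (standardized-age scale):\n")
  print(round(x$model$coefficients, 4))
  invisible(x)
}

#' @export
plot.cause_trajectory <- function(x, age = NULL, ...) {
  if (is.null(age)) {
    rng <- if (!is.null(x$age)) range(x$age)
           else x$center + c(-2, 2) * x$scale
    age <- seq(rng[1], rng[2], length.out = 200)
  }
  Pr <- predict_proportions(x, age)
  graphics::matplot(age, Pr, type = "l", lty = 1, xlab = "age (years)",
                    ylab = "proportion of deaths", ...)
  graphics::legend("topleft", legend = colnames(Pr), lty = 1,
                   col = seq_len(ncol(Pr)), cex = 0.8, bty = "n")
  invisible(x)
}

#' @export
simulate.cause_trajectory <- function(object, nsim = 1, seed = NULL,
                                      age = NULL, ...) {
  if (is.null(age)) age <- object$age
  if (is.null(age)) stop("supply ages to simulate at")
  simulate_causes(object, age, seed = seed)
}

#' Age at which a cause's predicted proportion peaks
#'
#' Scans a 0.1-year grid over `age_range` and refines the best interior
#' grid point by golden-section search; ties break toward the younger age.
#' A maximum on the range boundary, or an (numerically) flat trajectory, is
#' flagged.
#'
#' @param model a `cause_trajectory`.
#' @param cause which cause's trajectory to maximize.
#' @param age_range numeric `c(lo, hi)` in years.
#' @return List with `age`, `proportion`, `boundary` (logical), `flat`
#'   (logical).
#' @export
find_peak_age <- function(model, cause, age_range) {
  stopifnot(inherits(model, "cause_trajectory"), cause %in% model$labels,
            length(age_range) == 2, diff(age_range) > 0)
  grid <- seq(age_range[1], age_range[2], by = 0.1)
  if (grid[length(grid)] < age_range[2]) grid <- c(grid, age_range[2])
  p <- predict_proportions(model, grid)[, cause]
  flat <- diff(range(p)) < 1e-12
  i <- which.max(p)  # first maximum = youngest on ties
  if (flat)
    return(list(age = grid[1], proportion = p[1], boundary = FALSE,
                flat = TRUE))
  if (i == 1L || i == length(grid))
    return(list(age = grid[i], proportion = p[i], boundary = TRUE,
                flat = FALSE))
  opt <- stats::optimize(function(a) predict_proportions(model, a)[, cause],
                         lower = grid[i - 1], upper = grid[i + 1],
                         maximum = TRUE, tol = 1e-6)
  list(age = opt$maximum, proportion = opt$objective, boundary = FALSE,
       flat = FALSE)
}

#' Cross-species age scale from neoplastic-peak alignment
#'
#' Aligns the two cohorts' neoplastic death-proportion curves by the ratio
#' of their peak ages: the scale factor maps one "dog year" to
#' `human_peak / dog_peak` human years. Both peaks must be interior to
#' their search ranges.
#'
#' @param human_model,dog_model fitted `cause_trajectory` models.
#' @param cause cause whose peaks are aligned (default `"neoplastic"`).
#' @param human_range,dog_range age ranges to search (years); default the
#'   fitted age range of each model.
#' @return Object of class `age_scale`: `human_peak_age`, `dog_peak_age`,
#'   `scale_factor`.
#' @export
compute_age_scale <- function(human_model, dog_model, cause = "neoplastic",
                              human_range = NULL, dog_range = NULL) {
  stopifnot(cause %in% human_model$labels, cause %in% dog_model$labels)
  if (is.null(human_range)) human_range <- range(human_model$age)
  if (is.null(dog_range)) dog_range <- range(dog_model$age)
  ph <- find_peak_age(human_model, cause, human_range)
  pd <- find_peak_age(dog_model, cause, dog_range)
  if (ph$boundary || pd$boundary || ph$flat || pd$flat)
    stop("no interior ", cause, " peak in ",
         if (ph$boundary || ph$flat) "the first cohort" else "the second cohort",
         "; supply a manual scale factor instead")
  structure(list(human_peak_age = ph$age, dog_peak_age = pd$age,
                 scale_factor = ph$age / pd$age, cause = cause),
            class = "age_scale")
}

#' @export
print.age_scale <- function(x, digits = 4, ...) {
  cat("Age scale from", x$cause, "peak alignment:\n")
  cat("  peak ages:", signif(x$human_peak_age, digits), "vs",
      signif(x$dog_peak_age, digits), "years\n")
  cat("  one dog year ~", signif(x$scale_factor, digits), "human years\n")
  invisible(x)
}

logit2 <- function(p) log2(p / (1 - p))

#' Log2 odds ratio of a cause of death between cohorts
#'
#' \eqn{\mathrm{logit}_2(p_{human}(age)) -
#' \mathrm{logit}_2(p_{dog}(age / s))} where \eqn{s} is the age scale
#' factor and \eqn{\mathrm{logit}_2(p) = \log_2(p / (1 - p))}. Positive
#' values mean the cause is more likely in the first (human) cohort; a
#' value of k means a \eqn{2^k}-fold odds difference. Probabilities are
#' clipped to `[eps, 1 - eps]` before the logit; clipped evaluations are
#' flagged in the `"clipped"` attribute.
#'
#' @param human_model,dog_model fitted `cause_trajectory` models.
#' @param scale an [compute_age_scale()] result, or a bare numeric scale
#'   factor.
#' @param cause cause label present in both models.
#' @param human_age ages on the human scale (years, >= 0).
#' @param eps clipping bound (default 1e-6).
#' @return Numeric vector of log2 odds ratios with logical attribute
#'   `"clipped"`.
#' @export
log2_odds_ratio <- function(human_model, dog_model, scale, cause,
                            human_age, eps = 1e-6) {
  stopifnot(cause %in% human_model$labels, cause %in% dog_model$labels,
            all(human_age >= 0))
  s <- if (inherits(scale, "age_scale")) scale$scale_factor else scale
  stopifnot(is.numeric(s), s > 0)
  ph <- predict_proportions(human_model, human_age)[, cause]
  pd <- predict_proportions(dog_model, human_age / s)[, cause]
  clipped <- ph < eps | ph > 1 - eps | pd < eps | pd > 1 - eps
  ph <- pmin(pmax(ph, eps), 1 - eps)
  pd <- pmin(pmax(pd, eps), 1 - eps)
  structure(logit2(ph) - logit2(pd), clipped = clipped)
}

#' Bootstrap confidence band for a cause trajectory
#'
#' Nonparametric bootstrap over individuals: resamples the (age, cause)
#' pairs with replacement, refits the model, and takes percentile intervals
#' of the predicted proportion at each grid age.
#'
#' @param model a `cause_trajectory` fitted with data retained.
#' @param cause cause label.
#' @param age_grid ages at which the band is evaluated.
#' @param level coverage level (default 0.95).
#' @param B number of bootstrap replicates (>= 50, default 200).
#' @param seed RNG seed for reproducibility.
#' @return data.frame `age`, `estimate`, `lower`, `upper`.
#' @export
confidence_band <- function(model, cause, age_grid, level = 0.95, B = 200,
                            seed = NULL) {
  stopifnot(inherits(model, "cause_trajectory"), cause %in% model$labels,
            B >= 50, level > 0, level < 1)
  if (is.null(model$age)) stop("model carries no data to resample")
  if (!is.null(seed)) set.seed(seed)
  n <- length(model$age)
  # optim parameter layout is column-major P x (K-1); coefficients are
  # stored K x P with the reference first, so transpose and drop it
  start <- as.vector(t(model$coefficients[-1, , drop = FALSE]))
  boot <- matrix(NA_real_, B, length(age_grid))
  fails <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(
      suppressWarnings(fit_cause_trajectory(model$age[idx],
                                            model$cause[idx],
                                            degree = model$degree,
                                            ref = model$ref,
                                            start = start)),
      error = function(e) NULL)
    if (is.null(fit) || !setequal(fit$labels, model$labels)) {
      fails <- fails + 1L
      next
    }
    boot[b, ] <- predict_proportions(fit, age_grid)[, cause]
  }
  if (fails > 0.1 * B)
    stop("bootstrap refit failures exceeded 10% of replicates (",
         fails, "/", B, ")")
  a <- (1 - level) / 2
  est <- predict_proportions(model, age_grid)[, cause]
  lower <- apply(boot, 2, stats::quantile, probs = a, na.rm = TRUE)
  upper <- apply(boot, 2, stats::quantile, probs = 1 - a, na.rm = TRUE)
  data.frame(age = age_grid, estimate = est,
             lower = pmin(lower, est), upper = pmax(upper, est))
}
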