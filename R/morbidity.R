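# Multimorbidity = number of distinct diagnoses on a record at death.
# Comorbidity for an index condition = that count minus the index diagnosis
# itself on records carrying it. Counts are modelled with a negative
# binomial GLM (log link, variance mu + mu^2/theta).

diagnoses_list <- function(records) {
  lapply(strsplit(as.character(records$diagnoses), ";", fixed = TRUE),
         function(d) unique(normalize_dx(d)))
}

#' Multimorbidity count per record
#'
#' Number of distinct diagnoses recorded at death, each weighted equally
#' regardless of severity (duplicates within a record count once).
#'
#' @param records death-record data.frame.
#' @return Integer vector.
#' @export
multimorbidity <- function(records) {
  lengths(diagnoses_list(records))
}

#' Fit a negative-binomial count regression
#'
#' Log-link negative binomial GLM with dispersion `theta` estimated jointly
#' by maximum likelihood (variance \eqn{\mu + \mu^2/\theta}), via
#' [MASS::glm.nb()]. Wald z and p are reported per coefficient.
#'
#' @param formula model formula; the response must be a non-negative count.
#' @param data data.frame of covariates.
#' @return Object of class `count_model`: `coefficients` (data.frame term,
#'   estimate, se, z, p), `theta`, `logLik`, and the underlying `fit`.
#' @export
fit_negbin <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(y != round(y))) stop("response must be counts >= 0")
  if (stats::var(y) == 0) stop("zero-variance response")
  fit <- suppressWarnings(MASS::glm.nb(formula, data = data))
  if (!fit$converged) stop("negative-binomial fit did not converge")
  sm <- summary(fit)
  cf <- sm$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], z = cf[, 3], p = cf[, 4],
                              row.names = NULL),
    theta = fit$theta, logLik = as.numeric(stats::logLik(fit)),
    fit = fit, formula = formula),
    class = "count_model")
}

#' @export
coef.count_model <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.count_model <- function(object, ...) stats::logLik(object$fit)

#' @export
predict.count_model <- function(object, newdata,
                                type = c("response", "link"), ...) {
  stats::predict(object$fit, newdata = newdata, type = match.arg(type))
}

#' @export
print.count_model <- function(x, digits = 4, ...) {
  cat("Negative-binomial count model (log link), theta =",
      signif(x$theta, digits), "\n")
  print(x$coefficients, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.count_model <- function(object, ...) {
  print(object)
  invisible(object)
}

# covariate frame shared by the morbidity analyses; sex coded female=0, male=1
morbidity_frame <- function(records) {
  sex <- normalize_dx(as.character(records$sex))
  if (!all(sex %in% c("female", "male"))) stop("sex must be female/male")
  data.frame(age = as.numeric(records$age_years),
             sex = as.integer(sex == "male"))
}

#' Multimorbidity regression on age, sex and (optionally) cause category
#'
#' Models the per-record diagnosis count at death as a negative-binomial
#' GLM with age and sex as fixed effects, optionally adding the
#' pathophysiological-process or organ-system cause of death as a
#' categorical fixed effect. Categories with fewer than 2 records are
#' excluded with a warning. Records should be pre-filtered with
#' [filter_records()].
#'
#' @param records filtered death-record data.frame (deaths only are used).
#' @param category_axis `"none"`, `"pp"` or `"os"`.
#' @return A `count_model` with an extra `adjusted_means` component when a
#'   category axis is used: per-category mean count predicted at the
#'   sample-average age and sex mix.
#' @export
multimorbidity_analysis <- function(records,
                                    category_axis = c("none", "pp", "os")) {
  category_axis <- match.arg(category_axis)
  records <- records[records$event == 1, , drop = FALSE]
  d <- morbidity_frame(records)
  d$count <- multimorbidity(records)
  if (category_axis == "none") {
    return(fit_negbin(count ~ age + sex, d))
  }
  cat_col <- if (category_axis == "pp") "cause_pp" else "cause_os"
  d$category <- normalize_dx(as.character(records[[cat_col]]))
  small <- names(which(table(d$category) < 2))
  if (length(small)) {
    warning("excluding categories with < 2 records: ",
            paste(small, collapse = ", "))
    d <- d[!d$category %in% small, , drop = FALSE]
  }
  d$category <- stats::relevel(factor(d$category),
                               ref = sort(unique(d$category))[1])
  m <- fit_negbin(count ~ age + sex + category, d)
  nd <- data.frame(age = mean(d$age), sex = mean(d$sex),
                   category = levels(d$category))
  m$adjusted_means <- stats::setNames(
    as.numeric(stats::predict(m$fit, newdata = nd, type = "response")),
    levels(d$category))
  m$category_axis <- category_axis
  m
}

#' Comorbidity regression for an index condition
#'
#' For a specified index condition (e.g. obesity), models the number of
#' co-occurring diagnoses — for records carrying the condition the count
#' excludes the condition itself — as a negative-binomial GLM on the
#' condition indicator, age and sex. Reports adjusted mean comorbidity for
#' cases and non-cases at the sample-average age and sex mix.
#'
#' @param records filtered death-record data.frame.
#' @param condition index diagnosis string (case-insensitive).
#' @return A `count_model` with extra components `condition`, `n_cases`,
#'   and `adjusted_means` (named: `case`, `noncase`).
#' @export
comorbidity_analysis <- function(records, condition) {
  records <- records[records$event == 1, , drop = FALSE]
  dx <- diagnoses_list(records)
  cond <- normalize_dx(condition)
  flag <- vapply(dx, function(d) cond %in% d, logical(1))
  if (!any(flag))
    stop("condition '", condition, "' absent from every record")
  d <- morbidity_frame(records)
  d$has_condition <- as.integer(flag)
  d$count <- lengths(dx) - d$has_condition
  m <- fit_negbin(count ~ has_condition + age + sex, d)
  nd <- data.frame(has_condition = c(1, 0), age = mean(d$age),
                   sex = mean(d$sex))
  m$adjusted_means <- stats::setNames(
    as.numeric(stats::predict(m$fit, newdata = nd, type = "response")),
    c("case", "noncase"))
  m$condition <- condition
  m$n_cases <- sum(flag)
  m
}
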