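#' Per-cohort cause-of-death proportion table
#'
#' Tabulates death proportions over a cause axis for each cohort,
#' restricted to a shared category set and renormalized. The
#' `"cancer_os"` axis conditions on a neoplastic process and tabulates the
#' organ system in which the cancer occurred.
#'
#' @param records filtered death-record data.frame with a `cohort` column.
#' @param axis `"pp"`, `"os"` or `"cancer_os"`.
#' @param shared_categories categories to compare; default is the set
#'   present in every cohort, excluding `"unclassified"`.
#' @return Object of class `proportion_table`: data.frame `category` plus
#'   one proportion column per cohort; attribute `"axis"`.
#' @export
proportion_table <- function(records, axis = c("pp", "os", "cancer_os"),
                             shared_categories = NULL) {
  axis <- match.arg(axis)
  records <- records[records$event == 1, , drop = FALSE]
  pp <- normalize_dx(as.character(records$cause_pp))
  if (axis == "cancer_os")
    records <- records[pp == "neoplastic", , drop = FALSE]
  col <- if (axis == "pp") "cause_pp" else "cause_os"
  cat_vals <- normalize_dx(as.character(records[[col]]))
  cohort <- as.character(records$cohort)
  cohorts <- unique(cohort)
  if (is.null(shared_categories)) {
    per <- lapply(cohorts, function(ch) unique(cat_vals[cohort == ch]))
    shared_categories <- setdiff(Reduce(intersect, per), "unclassified")
  }
  shared_categories <- sort(normalize_dx(shared_categories))
  if (length(shared_categories) == 0) stop("no shared categories")
  out <- data.frame(category = shared_categories)
  for (ch in cohorts) {
    v <- cat_vals[cohort == ch]
    v <- v[v %in% shared_categories]
    tab <- table(factor(v, levels = shared_categories))
    out[[ch]] <- as.numeric(tab) / sum(tab)
  }
  structure(out, axis = axis, class = c("proportion_table", "data.frame"))
}

#' @export
print.proportion_table <- function(x, digits = 4, ...) {
  cat("Cause-of-death proportions (axis: ", attr(x, "axis"), ")\n",
      sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Spearman rank correlation of two cause-of-death spectra
#'
#' Spearman's rho with average ranks for ties; the p-value uses the exact
#' null distribution for 8 or fewer categories (where the large-sample
#' approximation is poor) and the t approximation above that. Category
#' exclusion (e.g. dropping vascular deaths) is a first-class argument.
#'
#' @param x,y named numeric vectors of per-category proportions (same
#'   names), or bare numeric vectors of equal length.
#' @param exclude category names to drop before correlating.
#' @return Object of class `rank_correlation`: `rho`, `p_value`, `n`,
#'   `excluded`.
#' @export
spearman_spectra <- function(x, y, exclude = NULL) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    stopifnot(setequal(names(x), names(y)))
    y <- y[names(x)]
    if (!is.null(exclude)) {
      keep <- !normalize_dx(names(x)) %in% normalize_dx(exclude)
      x <- x[keep]; y <- y[keep]
    }
  } else if (!is.null(exclude)) {
    stop("exclusion by label needs named vectors")
  }
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 categories after exclusion")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ties <- anyDuplicated(x) || anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (length(x) <= 8 && !ties)))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x),
                 excluded = if (is.null(exclude)) character(0) else exclude),
            class = "rank_correlation")
}

#' @export
print.rank_correlation <- function(x, digits = 4, ...) {
  cat("Spearman rank correlation: rho =", signif(x$rho, digits),
      ", p =", format.pval(x$p_value, digits = digits),
      ", n =", x$n, "categories\n")
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Age-relatedness classification of a cause of death
#'
#' A cause is called age-related when the absolute number of deaths from it
#' increases with age. This is operationalized — as a reproducible
#' surrogate for visual inspection of stacked density plots — as a
#' one-sided Mann-Kendall trend test on death counts over age bins,
#' restricted to bins past the cohort's first quartile of death ages (to
#' ignore the juvenile mortality mode).
#'
#' @param records filtered death-record data.frame (one cohort).
#' @param cause pathophysiological-process or organ-system label.
#' @param axis `"pp"` or `"os"`.
#' @param age_breaks bin edges in years; default 10 equal-width bins over
#'   the cohort's death-age range.
#' @return Object of class `age_relatedness`: `classification`
#'   (`"age-related"` / `"not age-related"`), `tau`, `p_value`, `counts`
#'   (data.frame of bin midpoints and death counts), `surrogate = TRUE`.
#' @export
age_relatedness <- function(records, cause, axis = c("pp", "os"),
                            age_breaks = NULL) {
  axis <- match.arg(axis)
  records <- records[records$event == 1, , drop = FALSE]
  col <- if (axis == "pp") "cause_pp" else "cause_os"
  ages_all <- as.numeric(records$age_years)
  is_cause <- normalize_dx(as.character(records[[col]])) ==
    normalize_dx(cause)
  ages <- ages_all[is_cause]
  if (length(ages) < 20)
    warning("fewer than 20 deaths from '", cause,
            "'; classification unstable")
  if (is.null(age_breaks))
    age_breaks <- seq(min(ages_all), max(ages_all) + 1e-9,
                      length.out = 11)
  mids <- (age_breaks[-1] + age_breaks[-length(age_breaks)]) / 2
  counts <- as.numeric(table(cut(ages, age_breaks, right = FALSE,
                                 include.lowest = TRUE)))
  q1 <- stats::quantile(ages_all, 0.25, names = FALSE)
  late <- mids >= q1
  ct <- counts[late]
  if (length(ct) >= 3 && stats::sd(ct) > 0) {
    kt <- suppressWarnings(
      stats::cor.test(seq_along(ct), ct, method = "kendall",
                      alternative = "greater"))
    tau <- unname(kt$estimate)
    p <- kt$p.value
  } else {
    tau <- 0
    p <- 1
  }
  structure(list(
    classification = if (tau > 0 && p < 0.05) "age-related"
                     else "not age-related",
    tau = tau, p_value = p,
    counts = data.frame(age_mid = mids, deaths = counts,
                        past_q1 = late),
    cause = cause, axis = axis, surrogate = TRUE),
    class = "age_relatedness")
}

#' @export
print.age_relatedness <- function(x, digits = 4, ...) {
  cat("Cause '", x$cause, "' (", x$axis, "): ", x$classification, "\n",
      sep = "")
  cat("  Mann-Kendall trend (late-life bins): tau =",
      signif(x$tau, digits), ", one-sided p =",
      format.pval(x$p_value, digits = digits), "\n")
  cat("  (trend-test surrogate for 'absolute deaths increase with age')\n")
  invisible(x)
}
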