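# Seeded generator of synthetic two-cohort death-record datasets carrying
# the statistical structure the analysis modules assume: Gompertz
# lifespans, softmax cause-of-death trajectories with a configurable
# neoplastic peak age, negative-binomial diagnosis counts, optional
# registry-style age binning, and contamination with unclassified and
# euthanasia-only records. It is a stand-in for restricted human-census and
# veterinary-registry data, not a clinical simulator.

#' Draw lifespans from a Gompertz hazard
#'
#' Inverse-CDF sampling (see [rgompertz()]) under an optional fixed seed.
#'
#' @param n number of lifespans.
#' @param alpha,beta Gompertz parameters (see [gompertz_hazard()]).
#' @param seed optional RNG seed.
#' @return Vector of ages at death (years).
#' @export
simulate_lifespans <- function(n, alpha, beta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rgompertz(n, alpha, beta)
}

#' Draw causes of death from a trajectory model
#'
#' Each death's cause is drawn from the model's predicted proportions at
#' its age.
#'
#' @param model a `cause_trajectory` (fitted or built with
#'   [trajectory_model()]).
#' @param ages ages at death (years).
#' @param seed optional RNG seed.
#' @return Character vector of cause labels.
#' @export
simulate_causes <- function(model, ages, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- predict_proportions(model, ages)
  u <- stats::runif(length(ages))
  idx <- rep(1L, length(ages))
  acc <- P[, 1]
  for (j in seq_len(ncol(P) - 1L)) {
    idx <- idx + (u > acc)
    acc <- acc + P[, j + 1L]
  }
  model$labels[pmin(idx, length(model$labels))]
}

#' Build a trajectory generator with a peaked cause
#'
#' Constructs a `cause_trajectory` whose `peak_cause` has a quadratic
#' (inverted-parabola) logit in raw age with vertex at `peak_age`, while
#' the other non-reference causes have constant logits. The quadratic is
#' re-expressed exactly on the standardized-age scale used by the model.
#'
#' @param causes cause labels; the first is the reference (logit 0).
#' @param peak_cause which cause gets the peaked trajectory.
#' @param peak_age raw age (years) of the logit vertex.
#' @param peak_width width parameter w (years): logit drops by 1 at
#'   `peak_age +- w`.
#' @param peak_height logit value at the vertex.
#' @param base_logits named constant logits for the remaining causes
#'   (default 0).
#' @param center,scale age standardization constants for the model.
#' @return A `cause_trajectory` generator.
#' @export
peaked_trajectory <- function(causes, peak_cause = "neoplastic", peak_age,
                              peak_width, peak_height = 0.5,
                              base_logits = NULL, center, scale) {
  stopifnot(peak_cause %in% causes, causes[1] != peak_cause,
            peak_width > 0, scale > 0)
  K <- length(causes)
  B <- matrix(0, K, 5, dimnames = list(causes, NULL))
  u <- (center - peak_age) / peak_width
  v <- scale / peak_width
  B[peak_cause, 1:3] <- c(peak_height - u^2, -2 * u * v, -v^2)
  if (!is.null(base_logits)) {
    stopifnot(all(names(base_logits) %in% causes))
    B[names(base_logits), 1] <- base_logits
  }
  trajectory_model(B, center = center, scale = scale)
}

#' Specify a synthetic cohort
#'
#' Bundles everything [simulate_cohort()] needs: sex mix, sex-specific
#' Gompertz lifespan parameters, a cause-of-death trajectory generator, a
#' negative-binomial morbidity model with index-condition effects,
#' contamination rates, and the age-recording mode.
#'
#' @param label cohort label (e.g. `"human"`, `"dog"`).
#' @param sex_mix probability of female (default 0.5).
#' @param gompertz list with `female` and `male` entries, each
#'   `c(alpha, beta)`.
#' @param trajectory a `cause_trajectory` generator over
#'   pathophysiological-process labels.
#' @param morbidity list: `intercept`, `age`, `sex` (log-link
#'   coefficients), `theta` (dispersion), `conditions` (named log-link
#'   effects of index conditions), `prevalences` (named, in `[0, 1]`).
#' @param contamination `c(unclassified = ..., euthanasia_only = ...)`
#'   fractions in `[0, 1]`.
#' @param age_mode `"exact"` or `"vmdb"` (collapse ages to bin midpoints).
#' @param taxonomy a [cause_taxonomy()] supplying the diagnosis vocabulary.
#' @param bin_scheme an [age_bin_scheme()] (used when `age_mode = "vmdb"`).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(label, sex_mix = 0.5, gompertz, trajectory,
                        morbidity = NULL,
                        contamination = c(unclassified = 0,
                                          euthanasia_only = 0),
                        age_mode = c("exact", "vmdb"),
                        taxonomy = default_taxonomy(),
                        bin_scheme = vmdb_bin_scheme()) {
  age_mode <- match.arg(age_mode)
  stopifnot(sex_mix >= 0, sex_mix <= 1,
            all(c("female", "male") %in% names(gompertz)),
            inherits(trajectory, "cause_trajectory"),
            inherits(taxonomy, "cause_taxonomy"),
            inherits(bin_scheme, "age_bin_scheme"))
  contamination <- c(unclassified = unname(contamination["unclassified"]),
                     euthanasia_only = unname(contamination["euthanasia_only"]))
  contamination[is.na(contamination)] <- 0
  stopifnot(all(contamination >= 0), sum(contamination) <= 1)
  if (is.null(morbidity))
    morbidity <- list(intercept = log(1.5), age = 0.05, sex = 0, theta = 2,
                      conditions = numeric(0), prevalences = numeric(0))
  stopifnot(morbidity$theta > 0,
            all(morbidity$prevalences >= 0),
            all(morbidity$prevalences <= 1),
            setequal(names(morbidity$conditions),
                     names(morbidity$prevalences)))
  structure(list(label = label, sex_mix = sex_mix, gompertz = gompertz,
                 trajectory = trajectory, morbidity = morbidity,
                 contamination = contamination, age_mode = age_mode,
                 taxonomy = taxonomy, bin_scheme = bin_scheme),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort spec '", x$label, "': Gompertz beta F/M = ",
      signif(x$gompertz$female["beta"], 4), "/",
      signif(x$gompertz$male["beta"], 4),
      ", causes: ", paste(x$trajectory$labels, collapse = ", "),
      ", age mode: ", x$age_mode, "\n", sep = "")
  invisible(x)
}

#' Draw diagnosis lists from the morbidity model
#'
#' Draws index-condition flags at their prevalences, then a
#' negative-binomial number of additional diagnoses with log-link mean
#' `exp(intercept + age*age_i + sex*sex_i + sum(condition effects))`; each
#' record's diagnosis list contains its primary cause diagnosis (so every
#' death has at least one diagnosis), its flagged index conditions, and
#' filler diagnoses sampled from the taxonomy vocabulary without
#' replacement within a record.
#'
#' @param spec a [cohort_spec()].
#' @param ages,sexes vectors (years; 0 = female, 1 = male).
#' @param primary_dx primary cause diagnosis per record.
#' @param seed optional RNG seed.
#' @param overflow what to do when a drawn count exceeds the vocabulary
#'   size: `"error"` (default), or `"cap"` to truncate the record at the
#'   full vocabulary (distinct-diagnosis counts are bounded by the
#'   vocabulary by construction).
#' @return List with `diagnoses` (";"-joined strings) and `flags` (matrix
#'   of index-condition indicators).
#' @export
simulate_morbidity <- function(spec, ages, sexes, primary_dx, seed = NULL,
                               overflow = c("error", "cap")) {
  overflow <- match.arg(overflow)
  stopifnot(inherits(spec, "cohort_spec"),
            length(ages) == length(sexes),
            length(primary_dx) == length(ages))
  if (!is.null(seed)) set.seed(seed)
  n <- length(ages)
  mb <- spec$morbidity
  conds <- names(mb$conditions)
  flags <- matrix(0L, n, length(conds), dimnames = list(NULL, conds))
  for (cn in conds)
    flags[, cn] <- stats::rbinom(n, 1, mb$prevalences[[cn]])
  eta <- mb$intercept + mb$age * ages + mb$sex * sexes
  if (length(conds))
    eta <- eta + as.numeric(flags %*% mb$conditions[conds])
  extra <- stats::rnbinom(n, size = mb$theta, mu = exp(eta))
  vocab <- spec$taxonomy$map$diagnosis
  diagnoses <- character(n)
  for (i in seq_len(n)) {
    base <- c(primary_dx[i], conds[flags[i, ] == 1])
    base <- unique(normalize_dx(base))
    n_fill <- max(extra[i] - (length(base) - 1L), 0L)
    pool <- setdiff(vocab, base)
    if (n_fill > length(pool)) {
      if (overflow == "error")
        stop("requested diagnosis count exceeds the taxonomy vocabulary")
      n_fill <- length(pool)
    }
    fill <- if (n_fill > 0) sample(pool, n_fill) else character(0)
    diagnoses[i] <- paste(c(base, fill), collapse = ";")
  }
  list(diagnoses = diagnoses, flags = flags)
}

# map a generated PP cause to a representative primary diagnosis
sample_primary_dx <- function(causes, taxonomy) {
  map <- taxonomy$map
  vapply(causes, function(pp) {
    pool <- map$diagnosis[map$pp == pp]
    if (length(pool) == 0)
      stop("taxonomy has no diagnosis for process '", pp, "'")
    if (length(pool) == 1) pool else sample(pool, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a full cohort of death records
#'
#' Composes the lifespan, cause and morbidity samplers, then applies age
#' binning (when `age_mode = "vmdb"`) and contamination. The three sampler
#' stages use seeds derived from `seed` by fixed offsets, so they form
#' independent reproducible streams. Deterministic per seed.
#'
#' @param spec a [cohort_spec()].
#' @param n number of records.
#' @param seed integer seed.
#' @return A death-record data.frame (columns `id`, `cohort`, `sex`,
#'   `age_years`, `age_bin`, `diagnoses`, `primary_diagnosis`, `cause_pp`,
#'   `cause_os`, `event`) with attributes `spec` and `seed`.
#' @export
simulate_cohort <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"), n >= 1)
  set.seed(seed)
  sex <- ifelse(stats::runif(n) < spec$sex_mix, "female", "male")
  age <- numeric(n)
  set.seed(seed + 1L)
  for (s in c("female", "male")) {
    i <- sex == s
    if (any(i)) {
      g <- spec$gompertz[[s]]
      age[i] <- rgompertz(sum(i), g[["alpha"]], g[["beta"]])
    }
  }
  set.seed(seed + 2L)
  cause_pp <- simulate_causes(spec$trajectory, age)
  primary <- sample_primary_dx(cause_pp, spec$taxonomy)
  dx_match <- match(primary, spec$taxonomy$map$diagnosis)
  cause_os <- spec$taxonomy$map$os[dx_match]
  morb <- simulate_morbidity(spec, age, as.integer(sex == "male"), primary,
                             seed = seed + 3L, overflow = "cap")
  age_bin <- rep("", n)
  if (spec$age_mode == "vmdb") {
    bins <- find_bin(age, spec$bin_scheme)
    age_bin <- spec$bin_scheme$bins$label[bins]
    age <- spec$bin_scheme$bins$midpoint_years[bins]
  }
  records <- data.frame(
    id = paste0(spec$label, "_", seq_len(n)),
    cohort = spec$label, sex = sex, age_years = age, age_bin = age_bin,
    diagnoses = morb$diagnoses, primary_diagnosis = primary,
    cause_pp = cause_pp, cause_os = cause_os, event = 1L,
    stringsAsFactors = FALSE)
  set.seed(seed + 4L)
  rates <- spec$contamination
  n_unc <- stats::rbinom(1, n, rates[["unclassified"]])
  pick <- sample.int(n, n_unc)
  records$cause_pp[pick] <- "unclassified"
  records$cause_os[pick] <- "unclassified"
  remaining <- setdiff(seq_len(n), pick)
  p_euth <- rates[["euthanasia_only"]]
  if (p_euth > 0 && length(remaining)) {
    # condition on not already contaminated so marginal rates match spec
    n_euth <- stats::rbinom(1, length(remaining),
                            p_euth / (1 - rates[["unclassified"]]))
    pick2 <- sample(remaining, min(n_euth, length(remaining)))
    records$diagnoses[pick2] <- "euthanasia"
    records$primary_diagnosis[pick2] <- "euthanasia"
  }
  attr(records, "spec") <- spec
  attr(records, "seed") <- seed
  records
}

#' Default human-like cohort specification
#'
#' Gompertz slopes 0.089 (female) and 0.080 (male) with baseline hazards
#' solved for median lifespans of 80 and 75 years; neoplastic death
#' proportion peaking at 53 years; exact ages.
#'
#' @param ... overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
human_cohort_spec <- function(...) {
  traj <- peaked_trajectory(
    causes = c("degenerative", "infectious", "neoplastic", "traumatic",
               "vascular"),
    peak_cause = "neoplastic", peak_age = 53, peak_width = 25,
    peak_height = 0.5,
    base_logits = c(infectious = -0.8, traumatic = -1, vascular = 0.2),
    center = 50, scale = 25)
  args <- utils::modifyList(list(
    label = "human",
    gompertz = list(
      female = c(alpha = gompertz_alpha_for_median(0.089, 80),
                 beta = 0.089),
      male = c(alpha = gompertz_alpha_for_median(0.080, 75),
               beta = 0.080)),
    trajectory = traj,
    morbidity = list(intercept = log(1.2), age = 0.01, sex = 0, theta = 2,
                     conditions = numeric(0), prevalences = numeric(0)),
    age_mode = "exact"), list(...))
  do.call(cohort_spec, args)
}

#' Default dog-like cohort specification
#'
#' Gompertz slopes 0.0214 (female) and 0.0219 (male) with baseline hazards
#' solved for a median lifespan of 12 years; neoplastic death proportion
#' peaking at 11.5 years; five index chronic conditions with elevated
#' comorbidity (chronic kidney disease null); registry-style binned ages
#' and contamination off by default.
#'
#' @param ... overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
dog_cohort_spec <- function(...) {
  traj <- peaked_trajectory(
    causes = c("degenerative", "infectious", "neoplastic", "traumatic",
               "vascular"),
    peak_cause = "neoplastic", peak_age = 11.5, peak_width = 5,
    peak_height = 0.5,
    base_logits = c(infectious = -0.3, traumatic = 0.1, vascular = -1.5),
    center = 8, scale = 4.5)
  args <- utils::modifyList(list(
    label = "dog",
    gompertz = list(
      female = c(alpha = gompertz_alpha_for_median(0.0214, 12),
                 beta = 0.0214),
      male = c(alpha = gompertz_alpha_for_median(0.0219, 12),
               beta = 0.0219)),
    trajectory = traj,
    morbidity = list(
      intercept = log(1.5), age = 0.05, sex = 0, theta = 2,
      conditions = c("diabetes mellitus" = log(1.8),
                     "arthritis" = log(2), "obesity" = log(2),
                     "hypothyroidism" = log(2),
                     "chronic kidney disease" = 0),
      prevalences = c("diabetes mellitus" = 0.03, "arthritis" = 0.08,
                      "obesity" = 0.06, "hypothyroidism" = 0.04,
                      "chronic kidney disease" = 0.05)),
    age_mode = "exact"), list(...))
  do.call(cohort_spec, args)
}
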