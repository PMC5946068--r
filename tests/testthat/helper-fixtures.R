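# shared fixtures, built in code

toy_taxonomy <- function() {
  cause_taxonomy(data.frame(
    diagnosis = c("lymphoma", "chronic kidney disease", "stroke",
                  "vehicular trauma", "pneumonia", "diabetes mellitus",
                  "obesity", "arthritis"),
    pp = c("neoplastic", "degenerative", "vascular", "traumatic",
           "infectious", "metabolic", "metabolic", "degenerative"),
    os = c("hematopoietic", "urogenital", "neurologic", "musculoskeletal",
           "respiratory", "endocrine", "endocrine", "musculoskeletal"),
    stringsAsFactors = FALSE))
}

# minimal death-record row constructor
make_record <- function(id, age = 10, sex = "female", cohort = "dog",
                        diagnoses = "lymphoma",
                        primary = strsplit(diagnoses, ";")[[1]][1],
                        pp = "neoplastic", os = "hematopoietic",
                        event = 1L, age_bin = "") {
  data.frame(id = id, cohort = cohort, sex = sex, age_years = age,
             age_bin = age_bin, diagnoses = diagnoses,
             primary_diagnosis = primary, cause_pp = pp, cause_os = os,
             event = event, stringsAsFactors = FALSE)
}

# two-cause constant-probability model: P(target) = p at every age
constant_two_cause_model <- function(p, target = "target",
                                     ref = "other") {
  B <- matrix(0, 2, 5, dimnames = list(c(ref, target), NULL))
  B[target, 1] <- log(p / (1 - p))
  trajectory_model(B, center = 10, scale = 5)
}

# independent multinomial log-likelihood evaluator (softmax from scratch,
# raw formula) used as an oracle against fit_cause_trajectory
oracle_multinom_ll <- function(intercepts, slopes, z, cause, labels) {
  # intercepts/slopes: per-label named vectors (reference included as 0s)
  ll <- 0
  for (i in seq_along(z)) {
    eta <- intercepts + slopes * z[i]
    p <- exp(eta) / sum(exp(eta))
    ll <- ll + log(p[[cause[i]]])
  }
  ll
}
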