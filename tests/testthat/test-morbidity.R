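test_that("intercept-only negative binomial recovers the sample mean", {
  set.seed(16)
  d <- data.frame(y = stats::rnbinom(5000, size = 2, mu = 3))
  m <- fit_negbin(y ~ 1, d)
  expect_equal(exp(coef(m)[["(Intercept)"]]), mean(d$y),
               tolerance = 1e-6)
  expect_error(fit_negbin(y ~ 1, data.frame(y = rep(3, 50))),
               "zero-variance")
  expect_error(fit_negbin(y ~ 1, data.frame(y = c(1.5, 2))), "counts")
})

test_that("simulated age effect is recovered and order-invariant", {
  set.seed(17)
  n <- 20000
  d <- data.frame(age = stats::runif(n, 0, 15),
                  sex = stats::rbinom(n, 1, 0.5))
  d$y <- stats::rnbinom(n, size = 2, mu = exp(0.5 + 0.05 * d$age))
  m <- fit_negbin(y ~ age + sex, d)
  a_hat <- coef(m)[["age"]]
  expect_gt(a_hat, 0.04)
  expect_lt(a_hat, 0.06)
  # MLE log-likelihood is at least that of the generating parameters
  ll_truth <- sum(stats::dnbinom(d$y, size = 2,
                                 mu = exp(0.5 + 0.05 * d$age),
                                 log = TRUE))
  expect_gte(as.numeric(m$logLik), ll_truth)
  # invariance to record order
  perm <- sample(n)
  m2 <- fit_negbin(y ~ age + sex, d[perm, ])
  expect_equal(coef(m), coef(m2), tolerance = 1e-8)
})

test_that("Poisson data drives the dispersion to the Poisson limit", {
  set.seed(18)
  d <- data.frame(age = stats::runif(8000, 0, 10))
  d$y <- stats::rpois(8000, exp(0.3 + 0.08 * d$age))
  m <- fit_negbin(y ~ age, d)
  expect_gt(m$theta, 50)
  pois <- stats::glm(y ~ age, poisson, d)
  se <- summary(pois)$coefficients[, 2]
  expect_true(all(abs(coef(m) - stats::coef(pois)) < se))
})

test_that("multimorbidity rises with age with no sex effect, as generated", {
  spec <- dog_cohort_spec()
  recs <- simulate_cohort(spec, 4000, seed = 19)
  flt <- filter_records(recs)
  m <- multimorbidity_analysis(flt$records, "none")
  cf <- m$coefficients
  expect_gt(cf$estimate[cf$term == "age"], 0)
  expect_lt(cf$p[cf$term == "age"], 0.01)
  expect_gt(cf$p[cf$term == "sex"], 0.05)
  # single-diagnosis deaths contribute multimorbidity 1
  expect_gte(min(multimorbidity(flt$records)), 1)
})

test_that("near-constant counts give near-zero covariate effects", {
  set.seed(20)
  n <- 2000
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- 3 + stats::rbinom(1, 1, 0.02)
    make_record(paste0("r", i), age = stats::runif(1, 1, 15),
                sex = sample(c("female", "male"), 1),
                diagnoses = paste(c("lymphoma", paste0("dx", seq_len(k - 1))),
                                  collapse = ";"))
  }))
  m <- multimorbidity_analysis(recs, "none")
  cf <- m$coefficients
  expect_lt(abs(cf$estimate[cf$term == "age"]), 0.01)
  expect_lt(abs(cf$estimate[cf$term == "sex"]), 0.05)
})

test_that("a doubled-mean category doubles its adjusted mean", {
  set.seed(21)
  n <- 6000
  os <- sample(c("hepatic", "cardiovascular", "respiratory"), n, TRUE)
  mu <- ifelse(os == "hepatic", 6, 3)
  counts <- pmax(stats::rnbinom(n, size = 5, mu = mu), 1)
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_record(paste0("r", i), age = stats::runif(1, 1, 15),
                sex = sample(c("female", "male"), 1), os = os[i],
                diagnoses = paste(paste0("dx", seq_len(counts[i])),
                                  collapse = ";"))
  }))
  m <- multimorbidity_analysis(recs, "os")
  am <- m$adjusted_means
  expect_equal(unname(am["hepatic"] / am["cardiovascular"]), 2,
               tolerance = 0.15)
})

test_that("comorbidity counts exclude the index condition", {
  rec <- make_record("r1", diagnoses = "obesity;arthritis;diabetes mellitus",
                     primary = "obesity", pp = "metabolic", os = "endocrine")
  recs <- rbind(rec, make_record("r2", diagnoses = "lymphoma;arthritis"),
                make_record("r3", diagnoses = "lymphoma"),
                make_record("r4", diagnoses = "obesity;lymphoma",
                            primary = "obesity"))
  m <- comorbidity_analysis(recs, "obesity")
  # case with 3 diagnoses analyzed for obesity has response 3 - 1 = 2
  resp <- m$fit$model$count
  flag <- m$fit$model$has_condition
  expect_equal(resp[flag == 1], multimorbidity(recs)[flag == 1] - 1)
  expect_equal(max(resp[flag == 1]), 2)
  expect_error(comorbidity_analysis(recs, "hypothyroidism"), "absent")
})

test_that("a doubled comorbidity mean yields a condition effect near log 2", {
  set.seed(22)
  n <- 4000
  flag <- stats::rbinom(n, 1, 0.3)
  comorb <- 1 + stats::rnbinom(n, size = 5, mu = 30 * (1 + flag))
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    dx <- c(if (flag[i]) "obesity", "indexcause",
            paste0("dx", seq_len(comorb[i] - 1)))
    make_record(paste0("r", i), age = stats::runif(1, 1, 15),
                sex = sample(c("female", "male"), 1),
                diagnoses = paste(dx, collapse = ";"),
                primary = "indexcause")
  }))
  m <- comorbidity_analysis(recs, "obesity")
  cf <- m$coefficients
  est <- cf$estimate[cf$term == "has_condition"]
  expect_equal(est, log((1 + 60) / (1 + 30)), tolerance = 0.08)
  expect_lt(cf$p[cf$term == "has_condition"], 1e-6)
  expect_equal(unname(m$adjusted_means["case"] /
                      m$adjusted_means["noncase"]),
               2, tolerance = 0.2)
})

test_that("an effect-free condition has a CI covering zero", {
  set.seed(23)
  n <- 3000
  flag <- stats::rbinom(n, 1, 0.3)
  comorb <- 1 + stats::rnbinom(n, size = 5, mu = 4)
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    dx <- c(if (flag[i]) "obesity", "indexcause",
            paste0("dx", seq_len(comorb[i] - 1)))
    make_record(paste0("r", i), age = stats::runif(1, 1, 15),
                sex = sample(c("female", "male"), 1),
                diagnoses = paste(dx, collapse = ";"),
                primary = "indexcause")
  }))
  m <- comorbidity_analysis(recs, "obesity")
  cf <- m$coefficients
  est <- cf$estimate[cf$term == "has_condition"]
  se <- cf$se[cf$term == "has_condition"]
  expect_lt(abs(est), 1.96 * se)
})
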