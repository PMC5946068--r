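test_that("lifespan sampler reproduces its survival function and reseeds", {
  s1 <- simulate_lifespans(500, 1e-4, 0.09, seed = 40)
  s2 <- simulate_lifespans(500, 1e-4, 0.09, seed = 40)
  expect_identical(s1, s2)
  x <- simulate_lifespans(1e5, 1e-4, 0.09, seed = 41)
  grid <- seq(0, 120, 1)
  emp <- vapply(grid, function(g) mean(x > g), numeric(1))
  expect_lt(max(abs(emp - gompertz_survival(grid, 1e-4, 0.09))), 0.01)
})

test_that("cause sampler follows the trajectory model's probabilities", {
  null2 <- constant_two_cause_model(0.5)
  cs <- simulate_causes(null2, stats::runif(10000, 0, 20), seed = 42)
  frac <- mean(cs == "target")
  expect_gt(frac, 0.49); expect_lt(frac, 0.51)
  # age-binned empirical fractions track the model within sampling error
  gen <- peaked_trajectory(c("other", "neoplastic"), peak_age = 10,
                           peak_width = 4, center = 9, scale = 4)
  set.seed(43)
  age <- stats::runif(30000, 0, 20)
  cs <- simulate_causes(gen, age, seed = 44)
  for (b in 0:9) {
    sel <- age >= 2 * b & age < 2 * (b + 1)
    obs <- sum(cs[sel] == "neoplastic")
    p <- mean(predict_proportions(gen, age[sel])[, "neoplastic"])
    pv <- stats::binom.test(obs, sum(sel), p)$p.value
    expect_gt(pv, 0.001)
  }
  expect_identical(simulate_causes(gen, age[1:50], seed = 9),
                   simulate_causes(gen, age[1:50], seed = 9))
})

test_that("morbidity sampler floors counts at one and keeps the primary", {
  spec <- dog_cohort_spec()
  n <- 2000
  ages <- stats::runif(n, 0.5, 16)
  sexes <- stats::rbinom(n, 1, 0.5)
  primary <- sample(spec$taxonomy$map$diagnosis, n, TRUE)
  mb <- simulate_morbidity(spec, ages, sexes, primary, seed = 45)
  counts <- lengths(strsplit(mb$diagnoses, ";"))
  expect_equal(min(counts), 1)
  hit <- mapply(function(d, p) p %in% strsplit(d, ";")[[1]],
                mb$diagnoses, tolower(primary))
  expect_true(all(hit))
  # positive age coefficient: mean count rises across age terciles
  ter <- cut(ages, stats::quantile(ages, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE)
  means <- tapply(counts, ter, mean)
  expect_true(all(diff(means) > 0))
})

test_that("a count demand beyond the vocabulary errors unless capped", {
  tiny <- cause_taxonomy(data.frame(
    diagnosis = c("lymphoma", "stroke"),
    pp = c("neoplastic", "vascular"),
    os = c("hematopoietic", "neurologic")))
  spec <- dog_cohort_spec(taxonomy = tiny,
                          morbidity = list(intercept = log(50), age = 0,
                                           sex = 0, theta = 5,
                                           conditions = numeric(0),
                                           prevalences = numeric(0)))
  expect_error(simulate_morbidity(spec, rep(5, 20), rep(0, 20),
                                  rep("lymphoma", 20), seed = 46),
               "vocabulary")
  capped <- simulate_morbidity(spec, rep(5, 20), rep(0, 20),
                               rep("lymphoma", 20), seed = 46,
                               overflow = "cap")
  expect_lte(max(lengths(strsplit(capped$diagnoses, ";"))), 2)
})

test_that("cohort simulation is deterministic with independent streams", {
  spec <- dog_cohort_spec()
  a <- simulate_cohort(spec, 300, seed = 47)
  b <- simulate_cohort(spec, 300, seed = 47)
  expect_identical(a, b)
  # changing the morbidity model must not alter the lifespans
  spec2 <- dog_cohort_spec(morbidity = list(intercept = log(4), age = 0,
                                            sex = 0.3, theta = 1,
                                            conditions = numeric(0),
                                            prevalences = numeric(0)))
  c2 <- simulate_cohort(spec2, 300, seed = 47)
  expect_identical(a$age_years, c2$age_years)
  expect_identical(a$cause_pp, c2$cause_pp)
  expect_false(identical(a$diagnoses, c2$diagnoses))
})

test_that("contamination rates surface in the filter report", {
  spec <- dog_cohort_spec()
  clean <- simulate_cohort(spec, 2000, seed = 48)
  expect_equal(sum(filter_records(clean)$report), 0L)
  dirty_spec <- dog_cohort_spec(
    contamination = c(unclassified = 0.1, euthanasia_only = 0.05))
  dirty <- simulate_cohort(dirty_spec, 10000, seed = 49)
  rep <- filter_records(dirty)$report
  expect_lt(abs(unname(rep["unclassified"]) / 10000 - 0.1), 0.01)
  expect_lt(abs(unname(rep["euthanasia_only"]) / 10000 - 0.05), 0.01)
})

test_that("registry binning replaces ages by bin midpoints", {
  spec <- dog_cohort_spec(age_mode = "vmdb")
  recs <- simulate_cohort(spec, 500, seed = 50)
  mids <- vmdb_bin_scheme()$bins$midpoint_years
  expect_true(all(recs$age_years %in% mids))
  expect_true(all(nzchar(recs$age_bin)))
})

test_that("records survive a CSV round trip unchanged", {
  spec <- dog_cohort_spec(contamination = c(unclassified = 0.05,
                                            euthanasia_only = 0.05))
  recs <- simulate_cohort(spec, 200, seed = 51)
  attr(recs, "spec") <- NULL; attr(recs, "seed") <- NULL
  path <- tempfile(fileext = ".csv")
  write_records(recs, path, header = "seed=51")
  back <- read_records(path, taxonomy = spec$taxonomy)
  expect_equal(nrow(attr(back, "rejects")), 0)
  attr(back, "rejects") <- NULL
  # censored-free simulated data: all fields preserved
  expect_equal(back$age_years, recs$age_years, tolerance = 1e-12)
  for (col in c("id", "cohort", "sex", "diagnoses", "primary_diagnosis",
                "cause_pp", "cause_os"))
    expect_equal(back[[col]], recs[[col]])
})
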