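# End-to-end orchestration: filter -> survival/Gompertz -> morbidity ->
# trajectories -> age rescaling -> odds ratios -> spectra comparison,
# mirroring the order of the underlying comparative analysis. Every
# numeric output carries a header comment with the seed and a config hash.

# small FNV-1a hash so outputs can be traced to a configuration
config_hash <- function(config) {
  # the output location is not part of the analysis identity
  config$out_dir <- NULL
  s <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble a pipeline configuration
#'
#' Exactly one of `records_file` and `simulation` must be supplied.
#'
#' @param records_file path to a death-record CSV, or `NULL`.
#' @param simulation list of named [cohort_spec()]s, or `NULL`; each cohort
#'   is simulated with `n_per_cohort` records.
#' @param n_per_cohort simulated records per cohort (default 5000).
#' @param taxonomy_file,bin_scheme_file optional CSV paths overriding the
#'   packaged defaults when reading records.
#' @param analyses which stages to run; any subset of `"survival"`,
#'   `"gompertz"`, `"morbidity"`, `"comorbidity"`, `"trajectories"`,
#'   `"comparison"`.
#' @param comorbidity_conditions index diagnoses for the comorbidity stage.
#' @param human_cohort label of the cohort treated as the human (reference)
#'   side of the cross-species comparison; default the first cohort.
#' @param bootstrap_B bootstrap replicates for trajectory confidence bands
#'   (0 disables bands).
#' @param seed integer seed used for every source of randomness.
#' @param out_dir output directory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(records_file = NULL, simulation = NULL,
                            n_per_cohort = 5000,
                            taxonomy_file = NULL, bin_scheme_file = NULL,
                            analyses = c("survival", "gompertz",
                                         "morbidity", "comorbidity",
                                         "trajectories", "comparison"),
                            comorbidity_conditions = c("diabetes mellitus",
                                                       "arthritis",
                                                       "obesity",
                                                       "hypothyroidism",
                                                       "chronic kidney disease"),
                            human_cohort = NULL, bootstrap_B = 0,
                            seed = 1, out_dir = tempfile("compmort_run_")) {
  if (is.null(records_file) == is.null(simulation))
    stop("supply exactly one of records_file / simulation")
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(records_file = records_file, simulation = simulation,
                 n_per_cohort = n_per_cohort, taxonomy_file = taxonomy_file,
                 bin_scheme_file = bin_scheme_file, analyses = analyses,
                 comorbidity_conditions = comorbidity_conditions,
                 human_cohort = human_cohort, bootstrap_B = bootstrap_B,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Simulation specs cannot be expressed in a config file; file-based
#' configs describe record-driven runs.
#'
#' @param path `.json` or `.yaml`/`.yml` file of [pipeline_config()]
#'   fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else stop("unsupported config format: ", ext)
  do.call(pipeline_config, lst)
}

write_stage_csv <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config_hash=%s", seed, hash), con)
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full comparative morbidity/mortality pipeline
#'
#' Loads or simulates records, filters them, and runs the requested
#' analysis stages, writing one CSV per stage plus a run log and a plain
#' text summary (per-cohort Gompertz slopes, sex contrasts, multimorbidity
#' and comorbidity tables, neoplastic peak ages, the age-scale factor and
#' the rank-correlation table) to the output directory. Any stage error
#' aborts the run with the stage name and leaves a `FAILED` marker file.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list of the fitted objects and tables
#'   (`records`, `filter_report`, `gompertz`, `sex_contrast`,
#'   `multimorbidity`, `comorbidity`, `trajectories`, `age_scale`,
#'   `odds_ratios`, `proportions`, `correlations`, `age_relatedness`,
#'   `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  hash <- config_hash(config)
  out <- list(files = character(0))
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_stage_csv(df, path, seed, hash)
    out$files <<- c(out$files, path)
    path
  }
  failed_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage '", name, "' failed: ",
                        conditionMessage(e)), failed_marker)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  summary_lines <- c("Comparative morbidity/mortality pipeline summary",
                     sprintf("seed: %d  config: %s", seed, hash), "")

  ## load or simulate ------------------------------------------------------
  records <- stage("input", {
    if (!is.null(config$simulation)) {
      specs <- config$simulation
      do.call(rbind, lapply(seq_along(specs), function(i) {
        simulate_cohort(specs[[i]], config$n_per_cohort,
                        seed = seed + 1000L * i)
      }))
    } else {
      taxonomy <- if (is.null(config$taxonomy_file)) default_taxonomy()
                  else read_taxonomy(config$taxonomy_file)
      scheme <- if (is.null(config$bin_scheme_file)) vmdb_bin_scheme()
                else read_bin_scheme(config$bin_scheme_file)
      read_records(config$records_file, taxonomy, scheme,
                   rejects_file = file.path(config$out_dir, "rejects.csv"))
    }
  })

  ## filter ----------------------------------------------------------------
  flt <- stage("filter", filter_records(records))
  out$records <- flt$records
  out$filter_report <- flt$report
  emit(data.frame(reason = names(flt$report),
                  removed = as.integer(flt$report)),
       "filter_report.csv")
  summary_lines <- c(summary_lines,
                     sprintf("records: %d read, %d retained (%s)",
                             nrow(records), nrow(flt$records),
                             paste(names(flt$report), flt$report,
                                   sep = "=", collapse = ", ")), "")
  rec <- flt$records
  cohorts <- unique(rec$cohort)
  human <- if (is.null(config$human_cohort)) cohorts[1]
           else config$human_cohort

  ## survival + sex contrast ----------------------------------------------
  if ("survival" %in% config$analyses) stage("survival", {
    km_rows <- list(); hz_rows <- list()
    out$sex_contrast <- list()
    for (ch in cohorts) {
      r <- rec[rec$cohort == ch, ]
      for (s in unique(r$sex)) {
        rs <- r[r$sex == s, ]
        km <- km_estimate(rs$age_years, rs$event)
        km_rows[[paste(ch, s)]] <- data.frame(
          cohort = ch, sex = s, age = km$time, survival = km$surv,
          lower = km$lower, upper = km$upper)
        hz <- smoothed_hazard(rs$age_years, rs$event)
        hz_rows[[paste(ch, s)]] <- data.frame(
          cohort = ch, sex = s, age = hz$grid, hazard = hz$hazard,
          bandwidth = hz$bandwidth)
      }
      if (length(unique(r$sex)) == 2) {
        ct <- two_group_hazard_ratio(r$age_years, r$event,
                                     r$sex == "male")
        out$sex_contrast[[ch]] <- ct
        summary_lines <- c(summary_lines, sprintf(
          "%s sex effect (male vs female): log HR = %.4f, p = %.4g",
          ch, ct$log_hr, ct$p_value))
      }
    }
    emit(do.call(rbind, km_rows), "survival_km.csv")
    emit(do.call(rbind, hz_rows), "hazard_smoothed.csv")
    summary_lines <- c(summary_lines, "")
  })

  ## Gompertz --------------------------------------------------------------
  if ("gompertz" %in% config$analyses) stage("gompertz", {
    rows <- list()
    out$gompertz <- list()
    scheme <- if (is.null(config$bin_scheme_file)) vmdb_bin_scheme()
              else read_bin_scheme(config$bin_scheme_file)
    for (ch in cohorts) for (s in unique(rec$sex[rec$cohort == ch])) {
      rs <- rec[rec$cohort == ch & rec$sex == s, ]
      binned <- nzchar(rs$age_bin)
      fit <- if (all(binned) && nrow(rs) > 0) {
        # binned ages: interval-censored likelihood over the bin bounds
        i <- match(normalize_dx(rs$age_bin),
                   normalize_dx(scheme$bins$label))
        fit_gompertz(lower = scheme$bins$lo_years[i],
                     upper = scheme$bins$hi_years[i])
      } else {
        fit_gompertz(rs$age_years, rs$event)
      }
      out$gompertz[[paste(ch, s, sep = "_")]] <- fit
      rows[[paste(ch, s)]] <- data.frame(
        cohort = ch, sex = s, alpha = fit$alpha, beta = fit$beta,
        logLik = fit$logLik, n = fit$n)
      summary_lines <- c(summary_lines, sprintf(
        "%s %s Gompertz: alpha = %.6g, beta (rate of aging) = %.4f",
        ch, s, fit$alpha, fit$beta))
    }
    emit(do.call(rbind, rows), "gompertz_fits.csv")
    summary_lines <- c(summary_lines, "")
  })

  ## morbidity -------------------------------------------------------------
  if ("morbidity" %in% config$analyses) stage("morbidity", {
    rows <- list()
    out$multimorbidity <- list()
    for (ch in cohorts) {
      r <- rec[rec$cohort == ch & rec$event == 1, ]
      m <- multimorbidity_analysis(r, "none")
      out$multimorbidity[[ch]] <- m
      rows[[ch]] <- cbind(cohort = ch, m$coefficients)
      agep <- m$coefficients$p[m$coefficients$term == "age"]
      sexp <- m$coefficients$p[m$coefficients$term == "sex"]
      summary_lines <- c(summary_lines, sprintf(
        "%s multimorbidity ~ age + sex: age p = %.3g, sex p = %.3g",
        ch, agep, sexp))
    }
    emit(do.call(rbind, rows), "multimorbidity.csv")
    summary_lines <- c(summary_lines, "")
  })

  ## comorbidity -----------------------------------------------------------
  if ("comorbidity" %in% config$analyses) stage("comorbidity", {
    rows <- list()
    out$comorbidity <- list()
    for (ch in cohorts) {
      r <- rec[rec$cohort == ch & rec$event == 1, ]
      for (cond in config$comorbidity_conditions) {
        m <- tryCatch(comorbidity_analysis(r, cond),
                      error = function(e) NULL)
        if (is.null(m)) next
        out$comorbidity[[paste(ch, cond, sep = "_")]] <- m
        est <- m$coefficients[m$coefficients$term == "has_condition", ]
        rows[[paste(ch, cond)]] <- data.frame(
          cohort = ch, condition = cond, n_cases = m$n_cases,
          estimate = est$estimate, se = est$se, p = est$p,
          mean_case = m$adjusted_means[["case"]],
          mean_noncase = m$adjusted_means[["noncase"]])
        summary_lines <- c(summary_lines, sprintf(
          "%s comorbidity, %s: effect = %.3f (p = %.3g), adjusted means %.2f vs %.2f",
          ch, cond, est$estimate, est$p,
          m$adjusted_means[["case"]], m$adjusted_means[["noncase"]]))
      }
    }
    if (length(rows)) emit(do.call(rbind, rows), "comorbidity.csv")
    summary_lines <- c(summary_lines, "")
  })

  ## trajectories, age scale, odds ratios ----------------------------------
  if ("trajectories" %in% config$analyses) stage("trajectories", {
    out$trajectories <- list()
    traj_rows <- list()
    for (ch in cohorts) {
      r <- rec[rec$cohort == ch & rec$event == 1, ]
      fit <- fit_cause_trajectory(r$age_years, r$cause_pp)
      out$trajectories[[ch]] <- fit
      grid <- seq(min(r$age_years), max(r$age_years), length.out = 60)
      P <- predict_proportions(fit, grid)
      for (cs in colnames(P)) {
        band <- if (config$bootstrap_B >= 50) {
          confidence_band(fit, cs, grid, B = config$bootstrap_B,
                          seed = seed + 7L)
        } else {
          data.frame(age = grid, estimate = P[, cs], lower = NA_real_,
                     upper = NA_real_)
        }
        traj_rows[[paste(ch, cs)]] <- cbind(cohort = ch, cause = cs, band)
      }
    }
    emit(do.call(rbind, traj_rows), "trajectories.csv")
    if (length(cohorts) >= 2 &&
        all(vapply(out$trajectories,
                   function(m) "neoplastic" %in% m$labels, logical(1)))) {
      other <- setdiff(cohorts, human)[1]
      sc <- compute_age_scale(out$trajectories[[human]],
                              out$trajectories[[other]])
      out$age_scale <- sc
      emit(data.frame(human_cohort = human, dog_cohort = other,
                      human_peak_age = sc$human_peak_age,
                      dog_peak_age = sc$dog_peak_age,
                      scale_factor = sc$scale_factor),
           "age_scale.csv")
      summary_lines <- c(summary_lines, sprintf(
        "neoplastic peak ages: %s %.2f, %s %.2f; scale factor = %.3f",
        human, sc$human_peak_age, other, sc$dog_peak_age,
        sc$scale_factor))
      shared <- intersect(out$trajectories[[human]]$labels,
                          out$trajectories[[other]]$labels)
      hr <- rec$age_years[rec$cohort == human]
      agrid <- seq(min(hr), max(hr), length.out = 60)
      or_rows <- lapply(shared, function(cs) {
        v <- log2_odds_ratio(out$trajectories[[human]],
                             out$trajectories[[other]], sc, cs, agrid)
        data.frame(cause = cs, human_age = agrid,
                   log2_or = as.numeric(v),
                   clipped = attr(v, "clipped"))
      })
      out$odds_ratios <- do.call(rbind, or_rows)
      emit(out$odds_ratios, "log2_odds_ratios.csv")
    }
    summary_lines <- c(summary_lines, "")
  })

  ## spectra comparison ----------------------------------------------------
  if ("comparison" %in% config$analyses && length(cohorts) >= 2)
    stage("comparison", {
      out$proportions <- list()
      out$correlations <- list()
      cor_rows <- list(); prop_rows <- list()
      for (ax in c("pp", "os", "cancer_os")) {
        pt <- tryCatch(proportion_table(rec, ax), error = function(e) NULL)
        if (is.null(pt) || nrow(pt) < 3) next
        out$proportions[[ax]] <- pt
        prop_rows[[ax]] <- cbind(axis = ax, as.data.frame(pt))
        ch2 <- setdiff(cohorts, human)[1]
        rc <- spearman_spectra(stats::setNames(pt[[human]], pt$category),
                               stats::setNames(pt[[ch2]], pt$category))
        out$correlations[[ax]] <- rc
        cor_rows[[ax]] <- data.frame(axis = ax, rho = rc$rho,
                                     p = rc$p_value, n = rc$n,
                                     excluded = "")
        summary_lines <- c(summary_lines, sprintf(
          "%s spectra: Spearman rho = %.3f, p = %.3g (n = %d)",
          ax, rc$rho, rc$p_value, rc$n))
        if (ax == "pp" && "vascular" %in% pt$category) {
          rc2 <- spearman_spectra(
            stats::setNames(pt[[human]], pt$category),
            stats::setNames(pt[[ch2]], pt$category),
            exclude = "vascular")
          out$correlations[["pp_no_vascular"]] <- rc2
          cor_rows[["pp_no_vascular"]] <- data.frame(
            axis = "pp", rho = rc2$rho, p = rc2$p_value, n = rc2$n,
            excluded = "vascular")
          summary_lines <- c(summary_lines, sprintf(
            "pp spectra without vascular: rho = %.3f, p = %.3g",
            rc2$rho, rc2$p_value))
        }
      }
      if (length(prop_rows))
        emit(do.call(rbind, prop_rows), "proportions.csv")
      if (length(cor_rows))
        emit(do.call(rbind, cor_rows), "spearman.csv")
      ar_rows <- list()
      for (ch in cohorts) {
        r <- rec[rec$cohort == ch, ]
        for (cs in setdiff(unique(r$cause_pp[r$event == 1]), NA)) {
          ar <- suppressWarnings(age_relatedness(r, cs, "pp"))
          ar_rows[[paste(ch, cs)]] <- data.frame(
            cohort = ch, cause = cs,
            classification = ar$classification, tau = ar$tau,
            p = ar$p_value)
        }
      }
      out$age_relatedness <- do.call(rbind, ar_rows)
      emit(out$age_relatedness, "age_relatedness.csv")
      summary_lines <- c(summary_lines, "")
    })

  ## logs ------------------------------------------------------------------
  writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))
  writeLines(c(sprintf("seed: %d", seed),
               sprintf("config_hash: %s", hash),
               sprintf("compmort version: %s",
                       as.character(utils::packageVersion("compmort"))),
               sprintf("R version: %s", R.version.string),
               sprintf("filter: %s",
                       paste(names(flt$report), flt$report, sep = "=",
                             collapse = ", "))),
             file.path(config$out_dir, "run_log.txt"))
  out$summary <- summary_lines
  invisible(out)
}
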