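# Death-record CSV contract: columns id, cohort, sex, age_years or age_bin,
# diagnoses (";"-separated within the cell), primary_diagnosis, event
# (1/death or 0/censored); optional cause_pp / cause_os (classified through
# the taxonomy when absent). Malformed rows are collected, never silently
# dropped.

#' Read death records from CSV
#'
#' Validates each row; rows failing validation are collected into the
#' `"rejects"` attribute (data.frame `row`, `reason`) rather than silently
#' dropped. Binned ages are resolved to representative ages through the
#' bin scheme; missing cause labels are classified from the primary
#' diagnosis through the taxonomy.
#'
#' @param path CSV file (lines starting with `#` are ignored).
#' @param taxonomy a [cause_taxonomy()] used when `cause_pp`/`cause_os`
#'   are absent (default [default_taxonomy()]).
#' @param scheme an [age_bin_scheme()] for resolving `age_bin` values
#'   (default [vmdb_bin_scheme()]).
#' @param rejects_file optional path; when given, rejected rows are also
#'   written there.
#' @return Validated death-record data.frame with attribute `"rejects"`.
#' @export
read_records <- function(path, taxonomy = default_taxonomy(),
                         scheme = vmdb_bin_scheme(), rejects_file = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         colClasses = "character")
  required <- c("id", "cohort", "sex", "diagnoses", "primary_diagnosis",
                "event")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!any(c("age_years", "age_bin") %in% names(raw)))
    stop("missing required column: age_years or age_bin")
  if (is.null(raw$age_years)) raw$age_years <- ""
  if (is.null(raw$age_bin)) raw$age_bin <- ""
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  sex <- normalize_dx(raw$sex)
  ev_raw <- normalize_dx(raw$event)
  event <- ifelse(ev_raw %in% c("1", "death"), 1L,
                  ifelse(ev_raw %in% c("0", "censored"), 0L, NA_integer_))
  has_age <- !is.na(raw$age_years) & nzchar(trimws(raw$age_years))
  has_bin <- !is.na(raw$age_bin) & nzchar(trimws(raw$age_bin))
  age <- suppressWarnings(as.numeric(raw$age_years))
  reason[!sex %in% c("female", "male")] <- "unknown sex value"
  reason[is.na(reason) & is.na(event)] <- "unknown event value"
  reason[is.na(reason) & has_age & has_bin] <-
    "both age_years and age_bin present"
  reason[is.na(reason) & !has_age & !has_bin] <- "no age information"
  reason[is.na(reason) & has_age & (is.na(age) | age < 0)] <-
    "invalid age_years"
  for (i in which(is.na(reason) & has_bin)) {
    age[i] <- tryCatch(assign_bin_midpoint(raw$age_bin[i], scheme),
                       error = function(e) NA_real_)
    if (is.na(age[i])) reason[i] <- "unknown age bin"
  }
  dx <- strsplit(raw$diagnoses, ";", fixed = TRUE)
  empty_dx <- !vapply(dx, function(d) any(nzchar(trimws(d))), logical(1))
  reason[is.na(reason) & event == 1 & empty_dx] <- "death with no diagnoses"
  has_pp <- !is.null(raw$cause_pp)
  cause_pp <- if (has_pp) normalize_dx(raw$cause_pp)
              else rep(NA_character_, n)
  cause_os <- if (!is.null(raw$cause_os)) normalize_dx(raw$cause_os)
              else rep(NA_character_, n)
  for (i in which(is.na(reason) & event == 1 &
                  (is.na(cause_pp) | !nzchar(cause_pp)))) {
    cls <- tryCatch(classify_record(dx[[i]], raw$primary_diagnosis[i],
                                    taxonomy),
                    error = function(e) NULL)
    if (is.null(cls)) {
      reason[i] <- "primary diagnosis not among diagnoses"
    } else {
      cause_pp[i] <- cls[["pp"]]
      cause_os[i] <- cls[["os"]]
    }
  }
  cause_pp[event == 0] <- NA_character_
  cause_os[event == 0] <- NA_character_
  ok <- is.na(reason)
  records <- data.frame(
    id = raw$id[ok], cohort = raw$cohort[ok], sex = sex[ok],
    age_years = age[ok], age_bin = raw$age_bin[ok],
    diagnoses = raw$diagnoses[ok],
    primary_diagnosis = raw$primary_diagnosis[ok],
    cause_pp = cause_pp[ok], cause_os = cause_os[ok], event = event[ok],
    stringsAsFactors = FALSE)
  rejects <- data.frame(row = which(!ok), reason = reason[!ok],
                        stringsAsFactors = FALSE)
  if (!is.null(rejects_file) && nrow(rejects) > 0)
    utils::write.csv(cbind(rejects, raw[!ok, , drop = FALSE]),
                     rejects_file, row.names = FALSE)
  attr(records, "rejects") <- rejects
  records
}

#' Write death records to CSV
#'
#' @param records death-record data.frame.
#' @param path output file.
#' @param header optional comment lines (without the leading `#`) written
#'   before the CSV header.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  utils::write.csv(records, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}
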