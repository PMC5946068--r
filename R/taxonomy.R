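#' Pathophysiological-process and organ-system category sets
#'
#' The two axes of the cause-of-death taxonomy used throughout the package.
#' The pathophysiological process (PP) describes the disease mechanism; the
#' organ system (OS) the primary anatomical system affected. Both axes carry
#' an additional `"unclassified"` label for diagnoses too vague to assign.
#'
#' @return Character vector of category labels (the `"unclassified"` label
#'   is appended last).
#' @export
pp_categories <- function() {
  c("congenital", "degenerative", "infectious", "inflammatory", "metabolic",
    "neoplastic", "toxic", "traumatic", "vascular", "unclassified")
}

#' @rdname pp_categories
#' @export
os_categories <- function() {
  c("cardiovascular", "dermatologic", "endocrine", "gastrointestinal",
    "hematopoietic", "hepatic", "musculoskeletal", "neurologic",
    "ophthalmologic", "respiratory", "urogenital", "unclassified")
}

normalize_dx <- function(x) {
  tolower(trimws(gsub("[[:space:]]+", " ", x)))
}

#' Construct a cause-of-death taxonomy
#'
#' A taxonomy is a lookup from diagnosis strings to a (PP, OS) pair. Matching
#' is case-insensitive after whitespace normalization. Diagnoses absent from
#' the lookup classify as `("unclassified", "unclassified")`.
#'
#' @param map data.frame with character columns `diagnosis`, `pp`, `os`.
#' @return An object of class `cause_taxonomy`.
#' @seealso [default_taxonomy()], [read_taxonomy()], [classify_record()]
#' @export
cause_taxonomy <- function(map) {
  stopifnot(is.data.frame(map), all(c("diagnosis", "pp", "os") %in% names(map)))
  map <- data.frame(
    diagnosis = normalize_dx(as.character(map$diagnosis)),
    pp = normalize_dx(as.character(map$pp)),
    os = normalize_dx(as.character(map$os)),
    stringsAsFactors = FALSE
  )
  bad_pp <- setdiff(unique(map$pp), pp_categories())
  if (length(bad_pp)) stop("unknown PP categories in taxonomy: ",
                           paste(bad_pp, collapse = ", "))
  bad_os <- setdiff(unique(map$os), os_categories())
  if (length(bad_os)) stop("unknown OS categories in taxonomy: ",
                           paste(bad_os, collapse = ", "))
  if (anyDuplicated(map$diagnosis))
    stop("duplicated diagnosis keys in taxonomy")
  structure(list(map = map), class = "cause_taxonomy")
}

#' @export
print.cause_taxonomy <- function(x, ...) {
  cat("Cause-of-death taxonomy:", nrow(x$map), "diagnoses ->",
      length(unique(x$map$pp)), "PP x", length(unique(x$map$os)),
      "OS categories\n")
  invisible(x)
}

#' Packaged default taxonomy
#'
#' A small editable diagnosis-to-(PP, OS) lookup covering the synthetic
#' generator's diagnosis vocabulary. It is a stand-in for the (unavailable)
#' registry coding of raw clinical diagnosis strings; users with real data
#' supply their own table via [read_taxonomy()].
#'
#' @return A `cause_taxonomy`.
#' @export
default_taxonomy <- function() {
  path <- system.file("extdata", "default_taxonomy.csv", package = "compmort")
  read_taxonomy(path)
}

#' Read a taxonomy from CSV
#'
#' @param path CSV file with columns `diagnosis,pp,os`.
#' @return A `cause_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  cause_taxonomy(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Classify a death record's cause from its primary diagnosis
#'
#' Looks up the pre-assigned primary diagnosis in the taxonomy; the other
#' diagnoses on the record do not enter the classification. Unknown diagnoses
#' classify as unclassified on both axes.
#'
#' @param diagnoses character vector of the record's diagnoses (length >= 1).
#' @param primary_diagnosis the single diagnosis designated as cause of death;
#'   must be among `diagnoses`.
#' @param taxonomy a [cause_taxonomy()].
#' @return Named character vector `c(pp = ..., os = ...)`.
#' @export
classify_record <- function(diagnoses, primary_diagnosis, taxonomy) {
  stopifnot(inherits(taxonomy, "cause_taxonomy"))
  if (length(diagnoses) == 0L) stop("invalid record: empty diagnosis list")
  dx <- normalize_dx(diagnoses)
  primary <- normalize_dx(primary_diagnosis)
  if (!primary %in% dx)
    stop("primary diagnosis '", primary_diagnosis, "' not among the diagnoses")
  i <- match(primary, taxonomy$map$diagnosis)
  if (is.na(i)) return(c(pp = "unclassified", os = "unclassified"))
  c(pp = taxonomy$map$pp[i], os = taxonomy$map$os[i])
}

#' Filter death records as in the registry morbidity analyses
#'
#' Removes deaths whose assigned cause is unclassified on either axis, and
#' records whose only diagnosis is euthanasia. A euthanasia diagnosis inside
#' a longer list is retained. Censored records (no cause labels) pass
#' through. Idempotent.
#'
#' @param records a death-record data.frame (see [read_records()] for the
#'   column contract).
#' @return List with `records` (kept rows) and `report`, a named integer
#'   vector of removal counts by reason (`unclassified`, `euthanasia_only`).
#' @export
filter_records <- function(records) {
  if (nrow(records) == 0L) {
    return(list(records = records,
                report = c(unclassified = 0L, euthanasia_only = 0L)))
  }
  dx_lists <- strsplit(as.character(records$diagnoses), ";", fixed = TRUE)
  is_death <- records$event == 1
  unclassified <- is_death &
    (normalize_dx(as.character(records$cause_pp)) == "unclassified" |
     normalize_dx(as.character(records$cause_os)) == "unclassified")
  unclassified[is.na(unclassified)] <- FALSE
  euth_only <- vapply(dx_lists, function(d) {
    d <- normalize_dx(d)
    length(d) == 1L && d == "euthanasia"
  }, logical(1))
  # one removal reason per record; unclassified takes precedence
  euth_only <- euth_only & !unclassified
  keep <- !(unclassified | euth_only)
  list(records = records[keep, , drop = FALSE],
       report = c(unclassified = sum(unclassified),
                  euthanasia_only = sum(euth_only)))
}

#' Construct an age-bin scheme
#'
#' Bins are half-open `[lo, hi)` intervals in years, ordered and disjoint;
#' the top bin may be open-ended (`hi = NA`) with a fixed representative
#' age. A bounded bin's midpoint defaults to `(lo + hi) / 2` but may be
#' overridden (the veterinary-registry scheme collapses its three youngest
#' bins to a common 0.25-year label).
#'
#' @param bins data.frame with columns `label`, `lo_years`, `hi_years`
#'   (`NA` for open-ended), and optionally `midpoint_years`.
#' @return An object of class `age_bin_scheme`.
#' @export
age_bin_scheme <- function(bins) {
  stopifnot(is.data.frame(bins),
            all(c("label", "lo_years", "hi_years") %in% names(bins)))
  bins$lo_years <- as.numeric(bins$lo_years)
  bins$hi_years <- as.numeric(bins$hi_years)
  if (is.null(bins$midpoint_years)) bins$midpoint_years <- NA_real_
  bins$midpoint_years <- as.numeric(bins$midpoint_years)
  auto <- is.na(bins$midpoint_years)
  bins$midpoint_years[auto] <- (bins$lo_years[auto] + bins$hi_years[auto]) / 2
  if (anyNA(bins$midpoint_years))
    stop("open-ended bins need an explicit midpoint_years")
  o <- order(bins$lo_years)
  bins <- bins[o, , drop = FALSE]
  bounded <- !is.na(bins$hi_years)
  if (any(bins$lo_years[bounded] >= bins$hi_years[bounded]))
    stop("bins must satisfy lo < hi")
  if (sum(!bounded) > 1L) stop("at most one open-ended bin")
  hi <- ifelse(is.na(bins$hi_years), Inf, bins$hi_years)
  if (nrow(bins) > 1L && any(bins$lo_years[-1] + 1e-12 < hi[-nrow(bins)]))
    stop("bins overlap")
  structure(list(bins = bins), class = "age_bin_scheme")
}

#' @export
print.age_bin_scheme <- function(x, ...) {
  cat("Age-bin scheme with", nrow(x$bins), "bins:\n")
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' The veterinary-registry (VMDB-style) age-bin scheme
#'
#' Ten bins with the three youngest (0-2 weeks, 2 weeks-2 months,
#' 2-6 months) all represented as 0.25 years, midpoints elsewhere, and the
#' open-ended over-15-years bin represented as 17.5 years.
#'
#' @return An `age_bin_scheme`.
#' @export
vmdb_bin_scheme <- function() {
  wk <- 7 / 365.25
  mo <- 1 / 12
  age_bin_scheme(data.frame(
    label = c("0-2 weeks", "2 weeks-2 months", "2-6 months", "6-12 months",
              "1-2 years", "2-4 years", "4-7 years", "7-10 years",
              "10-15 years", "over 15 years"),
    lo_years = c(0, 2 * wk, 2 * mo, 0.5, 1, 2, 4, 7, 10, 15),
    hi_years = c(2 * wk, 2 * mo, 0.5, 1, 2, 4, 7, 10, 15, NA),
    midpoint_years = c(0.25, 0.25, 0.25, 0.75, 1.5, 3, 5.5, 8.5, 12.5, 17.5),
    stringsAsFactors = FALSE
  ))
}

#' Read an age-bin scheme from CSV
#'
#' @param path CSV with columns `label,lo_years,hi_years,midpoint_years`
#'   (empty `hi_years` marks the open-ended top bin).
#' @return An `age_bin_scheme`.
#' @export
read_bin_scheme <- function(path) {
  age_bin_scheme(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Resolve an age interval or bin label to its representative age
#'
#' @param interval either a bin `label` present in the scheme, or a numeric
#'   `c(lo, hi)` interval (`hi = NA` or `Inf` for the open-ended bin) that
#'   matches a scheme bin exactly.
#' @param scheme an [age_bin_scheme()].
#' @return The bin's representative (midpoint) age in years.
#' @export
assign_bin_midpoint <- function(interval, scheme) {
  stopifnot(inherits(scheme, "age_bin_scheme"))
  b <- scheme$bins
  if (is.character(interval)) {
    i <- match(normalize_dx(interval), normalize_dx(b$label))
    if (is.na(i)) stop("unknown age bin label: ", interval)
    return(b$midpoint_years[i])
  }
  stopifnot(is.numeric(interval), length(interval) == 2L)
  hi <- interval[2]
  if (is.infinite(hi)) hi <- NA_real_
  same <- abs(b$lo_years - interval[1]) < 1e-9 &
    ((is.na(b$hi_years) & is.na(hi)) |
     (!is.na(b$hi_years) & !is.na(hi) & abs(b$hi_years - hi) < 1e-9))
  i <- which(same)
  if (length(i) != 1L)
    stop("interval [", interval[1], ", ", interval[2],
         ") does not match a scheme bin")
  b$midpoint_years[i]
}

#' Locate the scheme bin containing an exact age
#'
#' Used by the simulator to collapse exact ages to registry-style bins.
#'
#' @param age numeric vector of ages in years.
#' @param scheme an [age_bin_scheme()].
#' @return Integer vector of bin row indices into `scheme$bins`.
#' @export
find_bin <- function(age, scheme) {
  stopifnot(inherits(scheme, "age_bin_scheme"))
  b <- scheme$bins
  hi <- ifelse(is.na(b$hi_years), Inf, b$hi_years)
  idx <- vapply(age, function(a) {
    i <- which(a >= b$lo_years - 1e-12 & a < hi)
    if (length(i) == 0L) NA_integer_ else i[1]
  }, integer(1))
  if (anyNA(idx)) stop("some ages fall outside every bin")
  idx
}
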