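# Validation helpers shared by the exposure and mortality readers. Errors
# report 1-based data row numbers (header excluded), matching what a user sees
# in the file.

stop_rows <- function(msg, rows) {
  rows <- sort(unique(rows))
  shown <- if (length(rows) > 10) {
    paste0(paste(utils::head(rows, 10), collapse = ", "), ", ...")
  } else {
    paste(rows, collapse = ", ")
  }
  stop(msg, " (row", if (length(rows) > 1) "s", " ", shown, ")", call. = FALSE)
}

parse_iso_date <- function(x, what) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) stop_rows(paste0("unparseable ISO-8601 date in ", what), which(is.na(d)))
  d
}

check_dates_increasing <- function(dates, what) {
  dup <- duplicated(dates)
  if (any(dup)) {
    stop(what, ": duplicated date(s): ",
         paste(unique(format(dates[dup])), collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(dates, strictly = TRUE)) {
    stop_rows(paste0(what, ": dates not strictly increasing"),
              which(diff(as.numeric(dates)) <= 0) + 1L)
  }
}

#' Validate a daily exposure series
#'
#' Checks the invariants of the weather table: strictly increasing unique
#' dates, `tmin <= tmean <= tmax` on every row, humidity in (0, 100],
#' positive pressure, and non-negative pollutant values where present.
#' Missing pollutant cells are allowed (and preserved as `NA`, never zero).
#'
#' @param exposure A data.frame with columns `date`, `tmax`, `tmean`, `tmin`,
#'   `humidity`, `pressure` and optionally `pm10`, `o3`.
#' @return The validated data.frame, invisibly coerced to canonical column
#'   order with a `Date` date column.
#' @export
validate_exposure <- function(exposure) {
  need <- c("date", "tmax", "tmean", "tmin", "humidity", "pressure")
  miss <- setdiff(need, names(exposure))
  if (length(miss)) stop("exposure table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  exposure$date <- if (inherits(exposure$date, "Date")) exposure$date else
    parse_iso_date(exposure$date, "exposure")
  check_dates_increasing(exposure$date, "exposure")
  for (col in c("tmax", "tmean", "tmin", "humidity", "pressure")) {
    if (anyNA(exposure[[col]])) {
      stop_rows(paste0("missing values in required column '", col, "'"),
                which(is.na(exposure[[col]])))
    }
  }
  bad <- exposure$tmin > exposure$tmean | exposure$tmean > exposure$tmax
  if (any(bad)) stop_rows("temperature ordering violated (need tmin <= tmean <= tmax)",
                          which(bad))
  bad <- exposure$humidity <= 0 | exposure$humidity > 100
  if (any(bad)) stop_rows("humidity outside (0, 100]", which(bad))
  bad <- exposure$pressure <= 0
  if (any(bad)) stop_rows("non-positive air pressure", which(bad))
  for (col in c("pm10", "o3")) {
    if (is.null(exposure[[col]])) exposure[[col]] <- NA_real_
    bad <- !is.na(exposure[[col]]) & exposure[[col]] < 0
    if (any(bad)) stop_rows(paste0("negative ", col), which(bad))
  }
  exposure[, c("date", "tmax", "tmean", "tmin", "humidity", "pressure",
               "pm10", "o3")]
}

#' Read a daily weather/pollutant table
#'
#' CSV with header `date,tmax,tmean,tmin,humidity,pressure,pm10,o3`
#' (pollutant columns optional; blank cells become `NA`). Dates must be
#' ISO-8601. All exposure invariants are enforced on load.
#'
#' @param path Path to the CSV file.
#' @return A validated exposure data.frame.
#' @seealso [validate_exposure()], [write_exposure()]
#' @export
read_exposure <- function(path) {
  validate_exposure(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_exposure
#' @param exposure Exposure data.frame to write.
#' @export
write_exposure <- function(exposure, path) {
  exposure <- validate_exposure(exposure)
  exposure$date <- format(exposure$date, "%Y-%m-%d")
  utils::write.csv(exposure, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a daily cause-specific mortality table
#'
#' Wide layout: a `date` column plus one non-negative integer count column per
#' cause label. Dates must be strictly increasing and counts complete — a
#' missing cell is an error, not an implicit zero (zero-filling is the job of
#' [aggregate_deaths()], which knows which dates exist). When
#' `check_hierarchy = TRUE` and a taxonomy is supplied, any day on which a
#' sub-category count exceeds its parent main-category count raises an error;
#' the check is off by default because independently modelled (and
#' independently simulated) series need not nest.
#'
#' @param mortality Wide data.frame of daily counts.
#' @param taxonomy Optional taxonomy giving parent links for the hierarchy
#'   check.
#' @param check_hierarchy Enforce sub-category <= main-category per day?
#' @return The validated data.frame with a `Date` date column.
#' @export
validate_mortality <- function(mortality, taxonomy = NULL,
                               check_hierarchy = FALSE) {
  if (!"date" %in% names(mortality)) stop("mortality table needs a 'date' column",
                                          call. = FALSE)
  if (ncol(mortality) < 2L) stop("mortality table has no cause columns",
                                 call. = FALSE)
  mortality$date <- if (inherits(mortality$date, "Date")) mortality$date else
    parse_iso_date(mortality$date, "mortality")
  check_dates_increasing(mortality$date, "mortality")
  causes <- setdiff(names(mortality), "date")
  for (col in causes) {
    x <- mortality[[col]]
    if (anyNA(x)) stop_rows(paste0("missing counts for cause '", col, "'"),
                            which(is.na(x)))
    if (any(x < 0)) stop_rows(paste0("negative counts for cause '", col, "'"),
                              which(x < 0))
    if (any(x != round(x))) stop_rows(paste0("non-integer counts for cause '",
                                             col, "'"), which(x != round(x)))
    mortality[[col]] <- as.integer(round(x))
  }
  if (check_hierarchy && !is.null(taxonomy)) {
    for (i in seq_len(nrow(taxonomy))) {
      lab <- taxonomy$label[i]; par <- taxonomy$parent[i]
      if (is.na(par) || !lab %in% causes || !par %in% causes) next
      bad <- mortality[[lab]] > mortality[[par]]
      if (any(bad)) {
        stop_rows(paste0("sub-category '", lab, "' exceeds its main category '",
                         par, "'"), which(bad))
      }
    }
  }
  mortality
}

#' Read a daily mortality table
#'
#' Two layouts are supported. `format = "wide"` (the distributed form) is a
#' CSV of `date` plus one column per cause label. `format = "long"` is a
#' line-list-style CSV with columns `date,icd10,count`; each record is
#' assigned to every matching taxonomy category via [assign_cause()] and
#' aggregated to daily counts with zero fill (see [aggregate_deaths()]).
#'
#' @param path Path to the CSV file.
#' @param format `"wide"` or `"long"`.
#' @param taxonomy Taxonomy used for `format = "long"` assignment and for the
#'   optional hierarchy check.
#' @param check_hierarchy Passed to [validate_mortality()].
#' @return A validated wide mortality data.frame.
#' @export
read_mortality <- function(path, format = c("wide", "long"),
                           taxonomy = heat_taxonomy(),
                           check_hierarchy = FALSE) {
  format <- match.arg(format)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "long") {
    need <- c("date", "icd10", "count")
    if (!all(need %in% names(tab))) {
      stop("long-format mortality needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    tab <- aggregate_deaths(tab, taxonomy)
  }
  validate_mortality(tab, taxonomy, check_hierarchy)
}

#' @rdname read_mortality
#' @param mortality Wide mortality data.frame to write.
#' @export
write_mortality <- function(mortality, path, taxonomy = heat_taxonomy()) {
  mortality <- validate_mortality(mortality, taxonomy)
  mortality$date <- format(mortality$date, "%Y-%m-%d")
  utils::write.csv(mortality, path, row.names = FALSE)
  invisible(path)
}

#' Aggregate line-listed deaths to daily counts per cause
#'
#' Each record (one or more deaths with a single ICD-10 code on one date)
#' contributes its count to every taxonomy category whose range contains the
#' code, and always to "All cause" when that label is present in the taxonomy.
#' The output covers every date from the first to the last record
#' contiguously, zero-filled, with one column per taxonomy label.
#'
#' @param records data.frame with columns `date`, `icd10` and optionally
#'   `count` (default 1 per row).
#' @param taxonomy Taxonomy data.frame.
#' @return Wide daily mortality data.frame.
#' @export
aggregate_deaths <- function(records, taxonomy = heat_taxonomy()) {
  records$date <- if (inherits(records$date, "Date")) records$date else
    parse_iso_date(records$date, "records")
  if (is.null(records$count)) records$count <- 1L
  if (any(records$count < 0)) stop_rows("negative counts",
                                        which(records$count < 0))
  dates <- seq(min(records$date), max(records$date), by = "day")
  out <- data.frame(date = dates)
  intervals <- lapply(taxonomy$icd10_ranges, parsed_ranges)
  ords <- icd10_ordinal(icd10_stem(records$icd10))
  di <- match(records$date, dates)
  for (i in seq_len(nrow(taxonomy))) {
    lab <- taxonomy$label[i]
    iv <- intervals[[i]]
    member <- if (nrow(iv) == 0L) {
      # range-less categories ("All cause") take every record
      rep(identical(lab, "All cause"), length(ords))
    } else {
      vapply(ords, function(o) any(iv$start_ord <= o & o <= iv$end_ord),
             logical(1))
    }
    cnt <- integer(length(dates))
    if (any(member)) {
      agg <- tapply(records$count[member], di[member], sum)
      cnt[as.integer(names(agg))] <- as.integer(agg)
    }
    out[[lab]] <- cnt
  }
  out
}
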