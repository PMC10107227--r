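## Scan-table I/O, validation, filtering and the odd/even-day partition.
##
## A scan table is a long-format record of instantaneous scans: one row per
## (date, time, zone, species) with the number of individuals counted. Times
## live on a nominal 5-minute grid ("HH:MM", 24 h).

#' Construct a scan table from parsed columns
#'
#' Internal-facing constructor also used by the simulator. Performs no
#' filtering; it only canonicalizes types and sorts rows.
#'
#' @param date `Date` vector.
#' @param time character vector, canonical `"HH:MM"` 24-hour clock.
#' @param zone character vector of zone codes.
#' @param species character vector of species codes.
#' @param count integer vector of counts (>= 1).
#' @return a `scan_table`: a `data.frame` with those five columns, ordered by
#'   date, time, zone, species.
#' @export
new_scan_table <- function(date = as.Date(character()),
                           time = character(),
                           zone = character(),
                           species = character(),
                           count = integer()) {
  x <- data.frame(date = as.Date(date), time = as.character(time),
                  zone = as.character(zone), species = as.character(species),
                  count = as.integer(count), stringsAsFactors = FALSE)
  x <- x[order(x$date, x$time, x$zone, x$species), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("scan_table", "data.frame")
  x
}

## "HH:MM" -> minutes since midnight (assumes canonical form)
time_to_minutes <- function(time) {
  as.integer(substr(time, 1L, 2L)) * 60L + as.integer(substr(time, 4L, 5L))
}

## Parse free-form clock strings; returns canonical "HH:MM" or NA.
parse_clock_time <- function(x) {
  m <- regmatches(x, regexec("^\\s*([0-9]{1,2}):([0-9]{2})(:[0-9]{2})?\\s*$",
                             as.character(x)))
  vapply(m, function(g) {
    if (length(g) == 0L) return(NA_character_)
    h <- as.integer(g[2L]); mi <- as.integer(g[3L])
    if (is.na(h) || is.na(mi) || h > 23L || mi > 59L) return(NA_character_)
    sprintf("%02d:%02d", h, mi)
  }, character(1))
}

#' Read a long-format scan table from CSV
#'
#' The file must have header columns `date`, `time`, `zone`, `species`,
#' `count` (ISO-8601 dates, 24-hour `HH:MM` times). Rows whose date, time or
#' count cannot be parsed, and rows duplicating an earlier
#' (date, time, zone, species) key, are not silently dropped: they are
#' collected in a rejects report attached as `attr(x, "rejects")`. Zone and
#' species codes outside the standard sets are retained at this stage;
#' enforcing them is the job of [filter_scans()].
#'
#' @param path path to the CSV file.
#' @param species_attrs species-attribute table (used only for validation of
#'   its own invariants; unknown species codes in the scans are kept).
#' @return a `scan_table` with attribute `rejects`: a `data.frame` with
#'   columns `line` (1-based data-row number), `reason`, and the raw fields.
#' @export
read_scan_table <- function(path, species_attrs = species_attributes()) {
  validate_species_attributes(species_attrs)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  needed <- c("date", "time", "zone", "species", "count")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("scan CSV is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  if (n == 0L) {
    out <- new_scan_table()
    attr(out, "rejects") <- cbind(data.frame(line = integer(),
                                             reason = character()),
                                  raw[0, needed])
    return(out)
  }
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  time <- parse_clock_time(raw$time)
  count_num <- suppressWarnings(as.numeric(raw$count))
  count_ok <- !is.na(count_num) & is.finite(count_num) &
    count_num == round(count_num) & count_num >= 1
  zone <- trimws(raw$zone)
  species <- trimws(raw$species)

  reason <- rep(NA_character_, n)
  reason[!count_ok] <- "non-integer or non-positive count"
  reason[is.na(time)] <- "unparseable time"
  reason[is.na(as.character(raw$date)) | is.na(date)] <- "unparseable date"
  ok <- is.na(reason)
  key <- paste(date, time, zone, species, sep = "\r")
  key[!ok] <- paste0("bad", which(!ok))  # keep bad rows out of dedup
  dup <- ok & duplicated(key)
  reason[dup] <- "duplicate (date,time,zone,species) key"
  ok <- is.na(reason)

  out <- new_scan_table(date[ok], time[ok], zone[ok], species[ok],
                        as.integer(count_num[ok]))
  rejects <- cbind(data.frame(line = which(!ok),
                              reason = reason[!ok],
                              stringsAsFactors = FALSE),
                   raw[!ok, needed, drop = FALSE])
  rownames(rejects) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Write a scan table to CSV
#'
#' Round-trips losslessly with [read_scan_table()] for all retained fields.
#'
#' @param x a `scan_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("date", "time", "zone", "species",
                                        "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter a scan table to the study conditions
#'
#' Retains only records for the 12 focal species, months October-December,
#' times strictly before the morning cutoff (the word "before" makes the
#' boundary exclusive: a 09:00 scan is removed), the 11 standard zones, and
#' complete date/time fields. Filtering is total (never errors) and
#' idempotent. Because only focal-species records survive, every remaining
#' scan necessarily has at least one focal individual present.
#'
#' @param x a `scan_table`.
#' @param species character vector of focal species codes to keep.
#' @param zones character vector of zone codes to keep.
#' @param cutoff_time exclusive upper bound on the time of day, `"HH:MM"`.
#' @param months integer months to keep (default October-December).
#' @return the filtered `scan_table`.
#' @export
filter_scans <- function(x, species = focal_species(),
                         zones = standard_zones(),
                         cutoff_time = "09:00",
                         months = 10:12) {
  stopifnot(inherits(x, "scan_table"))
  cutoff <- time_to_minutes(parse_clock_time(cutoff_time))
  mon <- as.integer(format(x$date, "%m"))
  keep <- !is.na(x$date) & !is.na(x$time) &
    x$species %in% species &
    x$zone %in% zones &
    mon %in% months &
    time_to_minutes(x$time) < cutoff
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scan_table", "data.frame")
  attr(out, "rejects") <- attr(x, "rejects")
  out
}

#' Partition a scan table by day-of-month parity
#'
#' Splits records into a main partition (even days of the month) and a
#' validation partition (odd days). The two partitions are disjoint and their
#' union is the input; the split depends only on the date field, so it is
#' stable under record order.
#'
#' @param x a `scan_table` (normally already filtered).
#' @return a list with `scan_table` elements `main` (even days) and
#'   `validation` (odd days).
#' @export
partition_by_day_parity <- function(x) {
  stopifnot(inherits(x, "scan_table"))
  mday <- as.integer(format(x$date, "%d"))
  even <- mday %% 2L == 0L
  split_one <- function(keep) {
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("scan_table", "data.frame")
    out
  }
  list(main = split_one(even), validation = split_one(!even))
}

#' @export
print.scan_table <- function(x, ...) {
  cat(sprintf("<scan_table> %d records, %d dates, %d zones, %d species\n",
              nrow(x), length(unique(x$date)), length(unique(x$zone)),
              length(unique(x$species))))
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej) > 0) {
    cat(sprintf("  (%d rejected rows in attr(x, 'rejects'))\n", nrow(rej)))
  }
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}
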