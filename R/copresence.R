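## Binary presence construction, co-presence counts, and mixing/diversity
## summaries. The unit of observation throughout is the zone-scan: one
## (date, time, zone) triple with at least one focal individual present.

#' Build a binary presence table from a scan table
#'
#' One row per distinct (date, time, zone) triple in the input; a species
#' column is 1 iff a record with count >= 1 exists for that key. The raw
#' counts are kept alongside for the mixing summaries.
#'
#' @param x a filtered `scan_table`.
#' @param species character vector defining the column set (default the 12
#'   focal codes).
#' @return a `presence_table`: a list with `index` (a `data.frame` of
#'   `date`, `time`, `zone`), `presence` (0/1 integer matrix, rows matching
#'   `index`), `counts` (integer matrix of individuals) and `species`.
#' @export
presence_table <- function(x, species = focal_species()) {
  stopifnot(inherits(x, "scan_table"))
  if (any(!x$species %in% species)) {
    stop("scan table contains species outside the requested column set; ",
         "run filter_scans() first")
  }
  key <- paste(x$date, x$time, x$zone, sep = "\r")
  ukey <- unique(key)
  ri <- match(key, ukey)
  ci <- match(x$species, species)
  n <- length(ukey)
  P <- matrix(0L, n, length(species), dimnames = list(NULL, species))
  C <- P
  P[cbind(ri, ci)] <- 1L
  C[cbind(ri, ci)] <- x$count
  first <- !duplicated(key)
  index <- data.frame(date = x$date[first], time = x$time[first],
                      zone = x$zone[first], stringsAsFactors = FALSE)
  ord <- order(index$date, index$time, index$zone)
  out <- list(index = index[ord, , drop = FALSE],
              presence = P[ord, , drop = FALSE],
              counts = C[ord, , drop = FALSE],
              species = species)
  rownames(out$index) <- NULL
  class(out) <- "presence_table"
  out
}

#' @export
print.presence_table <- function(x, ...) {
  cat(sprintf("<presence_table> %d zone-scans x %d species (%d dates)\n",
              nrow(x$presence), length(x$species),
              length(unique(x$index$date))))
  invisible(x)
}

#' Raw co-presence counts between species pairs
#'
#' `counts[i, j]` is the number of zone-scans in which at least one
#' individual of both species i and j was present; the diagonal holds each
#' species' total number of presence rows. The matrix is symmetric.
#'
#' @param p a `presence_table`.
#' @return a symmetric integer matrix with species dimnames.
#' @export
copresence_counts <- function(p) {
  stopifnot(inherits(p, "presence_table"))
  M <- crossprod(p$presence)
  storage.mode(M) <- "integer"
  M
}

## Median with a configurable convention for even sample sizes: "lower" takes
## the lower of the two middle order statistics, "standard" their mean.
median_by <- function(x, type = c("lower", "standard")) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (type == "standard") return(stats::median(x))
  sort(x)[floor((length(x) + 1) / 2)]
}

#' Per-species mixing and diversity summary
#'
#' For each focal species, over the zone-scans in which it was present:
#' the median number of species present, the median focal group size, the
#' median total number of individuals, the median Shannon entropy
#' \eqn{H = -\sum p_k \log p_k} (natural log) of the individual counts in the
#' zone-scan, and the proportion of zone-scans in which the focal was the
#' only species present. The distribution of species-per-zone-scan over the
#' whole table is attached as `attr(x, "species_per_scan")`.
#'
#' @param p a `presence_table` (its `counts` matrix supplies group sizes).
#' @param median_type convention for even-length medians; `"lower"` (default)
#'   takes the lower middle order statistic.
#' @return a `data.frame` with one row per species: `species`, `n_scans`,
#'   `median_n_species`, `median_focal_count`, `median_total_individuals`,
#'   `median_entropy`, `prop_monospecific`. Species never present get NA
#'   summaries.
#' @export
mixing_summary <- function(p, median_type = c("lower", "standard")) {
  stopifnot(inherits(p, "presence_table"))
  median_type <- match.arg(median_type)
  n_species_row <- rowSums(p$presence)
  total_row <- rowSums(p$counts)
  H_row <- vegan::diversity(p$counts, index = "shannon")
  out <- data.frame(species = p$species,
                    n_scans = NA_integer_, median_n_species = NA_real_,
                    median_focal_count = NA_real_,
                    median_total_individuals = NA_real_,
                    median_entropy = NA_real_, prop_monospecific = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(p$species)) {
    rows <- p$presence[, i] == 1L
    out$n_scans[i] <- sum(rows)
    if (!any(rows)) next
    out$median_n_species[i] <- median_by(n_species_row[rows], median_type)
    out$median_focal_count[i] <- median_by(p$counts[rows, i], median_type)
    out$median_total_individuals[i] <- median_by(total_row[rows], median_type)
    out$median_entropy[i] <- median_by(H_row[rows], median_type)
    out$prop_monospecific[i] <- mean(n_species_row[rows] == 1L)
  }
  attr(out, "species_per_scan") <- table(n_species_row)
  out
}

#' Presence tabulations by zone and by time of morning
#'
#' Counts, per species, the number of zone-scans with the species present in
#' each zone and at each scan time. Column sums of the by-zone table equal
#' per-species presence totals.
#'
#' @param p a `presence_table`.
#' @return a list with integer matrices `by_zone` (species x zone) and
#'   `by_time` (species x time).
#' @export
usage_profiles <- function(p) {
  stopifnot(inherits(p, "presence_table"))
  tab <- function(f) {
    lev <- sort(unique(f))
    m <- matrix(0L, length(p$species), length(lev),
                dimnames = list(p$species, lev))
    for (j in seq_along(lev)) {
      m[, j] <- colSums(p$presence[f == lev[j], , drop = FALSE])
    }
    m
  }
  list(by_zone = tab(p$index$zone), by_time = tab(p$index$time))
}
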