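## Run segmentation, joining-event extraction, and construction of the
## regression design panels (co-presence, joining by species, joining by
## schema category).
##
## A "run" is a maximal sequence of scans of the same (date, zone) spaced
## exactly 5 minutes apart; joining is only evaluable inside runs. Within a
## run, for a focal species A and a predictor species B across adjacent scans
## t-1, t:
##   y_A[t] = 1  iff A absent at t-1 and present at t   ("A joins")
##   x_B[t] = 1  iff B present at both t-1 and t        ("B was there")
## The first timepoint of a run carries y = x = 0, reproducing the standard
## encodings y = (0,0,1,0), x = (0,1,1,0) for a 4-scan run.

sanitize_names <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' Segment presence rows into runs of 5-minute-adjacent scans
#'
#' Per (date, zone), finds maximal chains of scans whose times are on the
#' 5-minute grid and exactly 5 minutes apart. Singleton scans (no 5-minute
#' neighbour) and off-grid times are excluded: joining is not evaluable there.
#'
#' @param p a `presence_table`.
#' @return a `run_table`: a `data.frame` with columns `run_id`, `date`,
#'   `zone`, `time` and `.row` (row index into `p`), ordered by run and time;
#'   each run has length >= 2.
#' @export
segment_runs <- function(p) {
  stopifnot(inherits(p, "presence_table"))
  idx <- p$index
  minutes <- time_to_minutes(idx$time)
  on_grid <- minutes %% 5L == 0L
  rows <- which(on_grid)
  out <- list()
  run_id <- 0L
  for (grp in split(rows, list(idx$date[rows], idx$zone[rows]), drop = TRUE)) {
    grp <- grp[order(minutes[grp])]
    breaks <- c(0L, which(diff(minutes[grp]) != 5L), length(grp))
    for (k in seq_len(length(breaks) - 1L)) {
      chain <- grp[(breaks[k] + 1L):breaks[k + 1L]]
      if (length(chain) < 2L) next
      run_id <- run_id + 1L
      out[[run_id]] <- data.frame(run_id = run_id,
                                  date = idx$date[chain],
                                  time = idx$time[chain],
                                  zone = idx$zone[chain],
                                  .row = chain,
                                  stringsAsFactors = FALSE)
    }
  }
  runs <- if (length(out) == 0L) {
    data.frame(run_id = integer(), date = as.Date(character()),
               time = character(), zone = character(), .row = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  rownames(runs) <- NULL
  class(runs) <- c("run_table", "data.frame")
  runs
}

#' Joining indicator series for a focal species over one run
#'
#' @param presence 0/1 (or logical) presence of the focal at each scan of a
#'   run, length >= 2.
#' @return integer 0/1 series `y` of the same length: `y[1] = 0`; for t >= 2,
#'   `y[t] = 1` iff the focal was absent at t-1 and present at t.
#' @export
join_indicator_series <- function(presence) {
  presence <- as.integer(as.logical(presence))
  n <- length(presence)
  stopifnot(n >= 2L)
  c(0L, as.integer(presence[-1L] == 1L & presence[-n] == 0L))
}

#' Predictor indicator series for a candidate partner over one run
#'
#' @param presence 0/1 (or logical) presence of the predictor species at each
#'   scan of a run, length >= 2.
#' @return integer 0/1 series `x` of the same length: `x[1] = 0`; for t >= 2,
#'   `x[t] = 1` iff the predictor was present at both t-1 and t.
#' @export
predictor_indicator_series <- function(presence) {
  presence <- as.integer(as.logical(presence))
  n <- length(presence)
  stopifnot(n >= 2L)
  c(0L, as.integer(presence[-1L] == 1L & presence[-n] == 1L))
}

## Lagged presence over a run table: list(prev, cur, start) matrices/flags.
run_lagged_presence <- function(p, runs) {
  rows <- runs$.row
  n <- length(rows)
  start <- c(TRUE, runs$run_id[-1L] != runs$run_id[-n])
  prev_row <- c(NA_integer_, rows[-n])
  prev_row[start] <- NA_integer_
  cur <- p$presence[rows, , drop = FALSE]
  prev <- matrix(0L, n, ncol(cur), dimnames = dimnames(cur))
  ok <- !is.na(prev_row)
  prev[ok, ] <- p$presence[prev_row[ok], , drop = FALSE]
  list(cur = cur, prev = prev, start = start)
}

#' Extract all joining events
#'
#' One event per (focal A, predictor B, scan t) such that, within a run, A
#' was absent at t-1 and present at t while B was present at both t-1 and t.
#' Joins with no qualifying partner (the focal arrived at an empty zone, or
#' no other species spanned the adjacent pair) are emitted with `predictor =
#' NA` for audit.
#'
#' @param p a `presence_table`.
#' @param runs a `run_table` from [segment_runs()] (computed if missing).
#' @return a `data.frame` with columns `focal`, `predictor`, `date`, `time`,
#'   `zone`.
#' @export
extract_join_events <- function(p, runs = segment_runs(p)) {
  lp <- run_lagged_presence(p, runs)
  empty <- data.frame(focal = character(), predictor = character(),
                      date = as.Date(character()), time = character(),
                      zone = character(), stringsAsFactors = FALSE)
  if (nrow(runs) == 0L) return(empty)
  out <- list()
  for (a in seq_along(p$species)) {
    y <- !lp$start & lp$cur[, a] == 1L & lp$prev[, a] == 0L
    for (t in which(y)) {
      bs <- p$species[lp$cur[t, ] == 1L & lp$prev[t, ] == 1L]
      bs <- setdiff(bs, p$species[a])
      if (length(bs) == 0L) bs <- NA_character_
      out[[length(out) + 1L]] <- data.frame(
        focal = p$species[a], predictor = bs,
        date = runs$date[t], time = runs$time[t], zone = runs$zone[t],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$date, ev$time, ev$zone, ev$focal, ev$predictor), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}

## Bin "HH:MM" times into b-minute time-of-morning blocks ("HH:MM" of the
## block start); NULL keeps exact scan times as levels.
bin_times <- function(time, bin_minutes = NULL) {
  if (is.null(bin_minutes)) return(time)
  m <- (time_to_minutes(time) %/% bin_minutes) * bin_minutes
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

## Assemble a design panel data.frame with standard attributes.
new_design_panel <- function(y, X, zone, tod, date, focal, design_kind,
                             predictors) {
  panel <- data.frame(y = as.integer(y), X, check.names = FALSE,
                      stringsAsFactors = FALSE)
  panel$zone <- factor(zone)
  panel$tod <- factor(tod)
  panel$date <- factor(as.character(date))
  attr(panel, "focal") <- focal
  attr(panel, "design_kind") <- design_kind
  attr(panel, "predictors") <- predictors
  attr(panel, "degenerate") <- length(unique(panel$y)) < 2L
  class(panel) <- c("design_panel", "data.frame")
  panel
}

#' Build the co-presence design panel for one focal species
#'
#' One row per zone-scan; the response is the focal's presence and the 11
#' predictors are the other species' presence, with zone, time-of-morning and
#' date labels for the random intercepts.
#'
#' @param p a `presence_table`.
#' @param focal focal species code.
#' @param tod_bin_minutes optional width, in minutes, of the time-of-morning
#'   blocks used as random-effect levels; `NULL` (default) uses exact scan
#'   times.
#' @return a `design_panel` with `design_kind = "copresence"`. A panel whose
#'   response is constant is flagged via `attr(panel, "degenerate")`.
#' @export
build_copresence_design <- function(p, focal, tod_bin_minutes = NULL) {
  stopifnot(inherits(p, "presence_table"), focal %in% p$species)
  others <- setdiff(p$species, focal)
  new_design_panel(y = p$presence[, focal],
                   X = as.data.frame(p$presence[, others, drop = FALSE]),
                   zone = p$index$zone,
                   tod = bin_times(p$index$time, tod_bin_minutes),
                   date = p$index$date,
                   focal = focal, design_kind = "copresence",
                   predictors = others)
}

#' Build the joining design panel for one focal species
#'
#' Rows are run timepoints, concatenated across runs (and thus across zones
#' and dates, with zone, time-of-morning and date kept as random-intercept
#' labels). The response is the focal's joining indicator and each of the 11
#' predictors is the partner's adjacent-pair presence indicator. Timepoints
#' where the focal was already present at t-1 (and so could not join) are
#' retained with y = 0 by default, reproducing the reference encodings;
#' `drop_present = TRUE` restricts the panel to at-risk timepoints instead.
#'
#' @param p a `presence_table`.
#' @param focal focal species code.
#' @param runs a `run_table` (computed if missing).
#' @param drop_present drop timepoints where the focal was present at t-1.
#' @param tod_bin_minutes optional width, in minutes, of the time-of-morning
#'   blocks used as random-effect levels; `NULL` (default) uses exact scan
#'   times.
#' @return a `design_panel` with `design_kind = "joining"`; by default its
#'   row count equals the total number of run timepoints.
#' @export
build_join_design <- function(p, focal, runs = segment_runs(p),
                              drop_present = FALSE, tod_bin_minutes = NULL) {
  stopifnot(inherits(p, "presence_table"), focal %in% p$species)
  if (nrow(runs) == 0L) {
    stop("no runs of 5-minute-adjacent scans: joining panel is empty")
  }
  lp <- run_lagged_presence(p, runs)
  others <- setdiff(p$species, focal)
  y <- as.integer(!lp$start & lp$cur[, focal] == 1L & lp$prev[, focal] == 0L)
  X <- matrix(0L, nrow(runs), length(others),
              dimnames = list(NULL, others))
  for (b in others) {
    X[, b] <- as.integer(!lp$start & lp$cur[, b] == 1L & lp$prev[, b] == 1L)
  }
  keep <- if (drop_present) !(lp$prev[, focal] == 1L & !lp$start) else
    rep(TRUE, nrow(runs))
  new_design_panel(y = y[keep], X = as.data.frame(X[keep, , drop = FALSE]),
                   zone = runs$zone[keep],
                   tod = bin_times(runs$time[keep], tod_bin_minutes),
                   date = runs$date[keep],
                   focal = focal, design_kind = "joining",
                   predictors = others)
}

#' Re-encode a joining panel's predictors under a categorization schema
#'
#' Replaces the 11 per-species predictor columns by one 0/1 column per
#' category of the schema: a category column is 1 iff any non-focal member
#' species of that category satisfies the adjacent-pair presence rule (the
#' elementwise OR of the member columns). The focal species is excluded from
#' its own category, and categories left with no eligible member species are
#' omitted. Under the species schema the encoding is the identity.
#'
#' @param panel a joining `design_panel`.
#' @param schema a schema name (see [schema_names()]).
#' @param attrs species-attribute table.
#' @return a `design_panel` with one predictor column per encodable category;
#'   `attr(panel, "schema")` holds the schema name and
#'   `attr(panel, "category_members")` the per-category member species.
#' @export
encode_schema_predictors <- function(panel, schema,
                                     attrs = species_attributes()) {
  stopifnot(inherits(panel, "design_panel"))
  focal <- attr(panel, "focal")
  mapping <- resolve_schema(schema, focal = focal, attrs = attrs)
  cats <- schema_category_levels(schema, attrs)
  others <- attr(panel, "predictors")
  Xcols <- list()
  members <- list()
  for (cat in cats) {
    mem <- intersect(others, names(mapping)[mapping == cat])
    if (length(mem) == 0L) next
    col <- as.integer(rowSums(as.data.frame(panel)[, mem, drop = FALSE]) > 0L)
    nm <- if (schema == "species") mem else sanitize_names(cat)
    Xcols[[nm]] <- col
    members[[nm]] <- mem
  }
  out <- new_design_panel(y = panel$y, X = as.data.frame(Xcols),
                          zone = panel$zone, tod = panel$tod,
                          date = panel$date,
                          focal = focal, design_kind = "joining-schema",
                          predictors = names(Xcols))
  attr(out, "schema") <- schema
  attr(out, "category_members") <- members
  out
}

#' @export
print.design_panel <- function(x, ...) {
  cat(sprintf("<design_panel> focal %s, kind %s: %d rows, %d predictors%s\n",
              attr(x, "focal"), attr(x, "design_kind"), nrow(x),
              length(attr(x, "predictors")),
              if (isTRUE(attr(x, "degenerate"))) " [degenerate response]"
              else ""))
  invisible(x)
}
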