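# Chain-enumeration oracle: maximal runs of 5-minute-adjacent times.
enumerate_runs <- function(minutes) {
  minutes <- sort(unique(minutes))
  runs <- list()
  cur <- minutes[1]
  for (m in minutes[-1]) {
    if (m - cur[length(cur)] == 5) cur <- c(cur, m)
    else {
      runs[[length(runs) + 1]] <- cur
      cur <- m
    }
  }
  runs[[length(runs) + 1]] <- cur
  Filter(function(r) length(r) >= 2, runs)
}

test_that("run segmentation finds maximal 5-minute chains", {
  mk <- function(times) {
    presence_table(read_scan_table(write_scan_csv(scan_df(
      date = "2010-10-22", time = times, zone = "1A", species = "RB",
      count = "1"))))
  }
  r1 <- segment_runs(mk(c("05:35", "05:40", "05:45", "05:50")))
  expect_equal(length(unique(r1$run_id)), 1L)
  expect_equal(nrow(r1), 4L)

  r2 <- segment_runs(mk(c("05:35", "05:45")))  # 10-minute gap
  expect_equal(nrow(r2), 0L)

  r3 <- segment_runs(mk(c("05:35", "05:40", "06:00", "06:05")))
  expect_equal(length(unique(r3$run_id)), 2L)
  expect_equal(as.integer(table(r3$run_id)), c(2L, 2L))

  # off-grid times are excluded from segmentation
  r4 <- segment_runs(mk(c("05:35", "05:38", "05:40")))
  expect_equal(nrow(r4), 2L)
  expect_false("05:38" %in% r4$time)

  # random times vs the enumeration oracle
  set.seed(4)
  for (rep in 1:10) {
    mins <- sort(sample(seq(300, 500, 5), 12))
    times <- sprintf("%02d:%02d", mins %/% 60, mins %% 60)
    runs <- segment_runs(mk(times))
    oracle <- enumerate_runs(mins)
    expect_equal(length(unique(runs$run_id)), length(oracle))
    expect_equal(nrow(runs), sum(lengths(oracle)))
  }
})

test_that("runs never span dates or zones", {
  st <- read_scan_table(write_scan_csv(scan_df(
    date = c("2010-10-22", "2010-10-22", "2010-10-23", "2010-10-23"),
    time = c("05:40", "05:45", "05:40", "05:45"),
    zone = c("1A", "2C", "1A", "1A"),
    species = "RB", count = "1")))
  runs <- segment_runs(presence_table(st))
  expect_equal(length(unique(runs$run_id)), 1L)
  expect_true(all(runs$date == as.Date("2010-10-23")))
})

test_that("joining and predictor indicator series match the printed encodings", {
  expect_equal(join_indicator_series(c(0, 0, 1, 1)), c(0L, 0L, 1L, 0L))
  expect_equal(predictor_indicator_series(c(1, 1, 1, 0)), c(0L, 1L, 1L, 0L))
  expect_equal(join_indicator_series(rep(1, 6)), rep(0L, 6))
  expect_equal(predictor_indicator_series(rep(0, 6)), rep(0L, 6))

  # brute-force pairwise oracle on random series
  set.seed(7)
  for (rep in 1:10) {
    pres <- rbinom(50, 1, 0.4)
    y <- join_indicator_series(pres)
    x <- predictor_indicator_series(pres)
    expect_equal(y[1], 0L)
    expect_equal(x[1], 0L)
    for (t in 2:50) {
      expect_equal(y[t], as.integer(pres[t - 1] == 0 && pres[t] == 1))
      expect_equal(x[t], as.integer(pres[t - 1] == 1 && pres[t] == 1))
    }
  }
})

test_that("join events reproduce the worked example and a brute-force scan", {
  p <- presence_table(fig_joining_scans())
  ev <- extract_join_events(p)
  expect_true(any(ev$focal == "RB" & ev$predictor == "BH" &
                    ev$time == "05:40" & ev$zone == "1A"))
  expect_true(any(ev$focal == "RB" & ev$predictor == "SC" &
                    ev$time == "05:40" & ev$zone == "1A"))
  # BH and SC were present from the first scan: they never join here
  expect_false(any(ev$focal %in% c("BH", "SC"), na.rm = TRUE))

  # focal always present: no events
  st <- read_scan_table(write_scan_csv(scan_df(
    date = "2010-10-22", time = c("05:40", "05:45", "05:50"), zone = "1A",
    species = "RB", count = "1")))
  expect_equal(nrow(extract_join_events(presence_table(st))), 0L)

  # three-species toy over six scans vs brute-force cross-product scan
  p3 <- presence_table(filter_scans(random_scan_table(
    seed = 21, n = 50, dates = as.Date("2010-10-22"),
    times = sprintf("05:%02d", seq(0, 25, 5)), zones = "1A",
    species = c("RB", "CF", "BH"))))
  ev3 <- extract_join_events(p3)
  ev3 <- ev3[!is.na(ev3$predictor), ]
  runs <- segment_runs(p3)
  expected <- 0L
  for (rid in unique(runs$run_id)) {
    rows <- runs$.row[runs$run_id == rid]
    pres <- p3$presence[rows, , drop = FALSE]
    for (a in p3$species) for (b in setdiff(p3$species, a)) {
      for (t in 2:length(rows)) {
        if (pres[t - 1, a] == 0 && pres[t, a] == 1 &&
            pres[t - 1, b] == 1 && pres[t, b] == 1) {
          expected <- expected + 1L
          expect_true(any(ev3$focal == a & ev3$predictor == b &
                            ev3$time == runs$time[runs$run_id == rid][t]))
        }
      }
    }
  }
  expect_equal(nrow(ev3), expected)
})

test_that("co-presence design panels are hand-checkable", {
  st <- read_scan_table(write_scan_csv(scan_df(
    date = "2010-10-22", time = c("05:40", "05:40", "05:45"),
    zone = c("1A", "1A", "1A"),
    species = c("RB", "CF", "RB"), count = "1")))
  p <- presence_table(st)
  panel <- build_copresence_design(p, "RB")
  expect_equal(panel$y, c(1L, 1L))
  expect_equal(panel$CF, c(1L, 0L))
  expect_equal(length(attr(panel, "predictors")), 11L)
  expect_true(isTRUE(attr(panel, "degenerate")))  # focal present everywhere

  full <- presence_table(filter_scans(random_scan_table(seed = 2, n = 80)))
  for (focal in c("RB", "SC")) {
    expect_equal(length(attr(build_copresence_design(full, focal),
                             "predictors")), 11L)
  }
})

test_that("joining design panels encode runs correctly and conserve joins", {
  p <- presence_table(fig_joining_scans())
  panel <- build_join_design(p, "RB")
  expect_equal(panel$y, c(0L, 0L, 1L, 0L))
  expect_equal(panel$BH, c(0L, 1L, 1L, 0L))
  expect_equal(panel$SC, c(0L, 1L, 1L, 0L))

  # row count equals the total number of run timepoints; join conservation
  pr <- presence_table(filter_scans(random_scan_table(seed = 13, n = 90)))
  runs <- segment_runs(pr)
  ev <- extract_join_events(pr, runs)
  for (focal in pr$species) {
    panel_f <- build_join_design(pr, focal, runs)
    expect_equal(nrow(panel_f), nrow(runs))
    n_events <- length(unique(paste(
      ev$date[ev$focal == focal], ev$time[ev$focal == focal],
      ev$zone[ev$focal == focal])))
    expect_equal(sum(panel_f$y), n_events)
  }

  # a focal absent everywhere gives an all-zero (degenerate) response
  panel_sc <- build_join_design(p, "ME")
  expect_true(isTRUE(attr(panel_sc, "degenerate")))
  expect_equal(sum(panel_sc$y), 0L)

  # dropping already-present timepoints keeps only the at-risk rows
  fig <- presence_table(fig_joining_scans())
  at_risk <- build_join_design(fig, "RB", drop_present = TRUE)
  expect_equal(nrow(at_risk), 3L)  # the post-arrival 4th scan is removed
  expect_equal(at_risk$y, c(0L, 0L, 1L))

  # time-of-morning binning coarsens the random-effect levels
  binned <- build_join_design(fig, "RB", tod_bin_minutes = 30)
  expect_equal(levels(binned$tod), "05:30")
  expect_equal(nlevels(build_join_design(fig, "RB")$tod), 4L)

  # no runs at all is an error
  lone <- presence_table(read_scan_table(write_scan_csv(scan_df(
    date = "2010-10-22", time = c("05:40", "06:00"), zone = "1A",
    species = "RB", count = "1"))))
  expect_error(build_join_design(lone, "RB"), "no runs")
})

test_that("schema encoding is the OR of member columns, focal excluded", {
  pr <- presence_table(filter_scans(random_scan_table(
    seed = 17, n = 150, species = c("BH", "OC", "WB", "RB", "SC", "ME"))))
  panel <- build_join_design(pr, "BH")
  enc <- encode_schema_predictors(panel, "clade")
  # for focal BH (a small parrot) the small-parrot column is the OR of the
  # other small parrots, OC and WB
  expect_true("small_parrot" %in% names(enc))
  expect_equal(enc$small_parrot, pmax(panel$OC, panel$WB))
  # every category column is the OR of its member species columns
  members <- attr(enc, "category_members")
  for (cat in names(members)) {
    oracle <- as.integer(rowSums(
      as.data.frame(panel)[, members[[cat]], drop = FALSE]) > 0)
    expect_equal(enc[[cat]], oracle)
    expect_false("BH" %in% members[[cat]])
    # coarse-graining monotonicity
    on <- enc[[cat]] == 1
    expect_true(all(rowSums(
      as.data.frame(panel)[on, members[[cat]], drop = FALSE]) >= 1))
  }

  # a category containing only the focal is omitted: OC is the only
  # black-headed species, so head_colour for focal OC has no black column
  panel_oc <- build_join_design(pr, "OC")
  enc_oc <- encode_schema_predictors(panel_oc, "head_colour")
  expect_false("black" %in% names(enc_oc))

  # the species schema is the identity coarse-graining
  enc_sp <- encode_schema_predictors(panel, "species")
  expect_equal(attr(enc_sp, "predictors"), attr(panel, "predictors")[
    order(match(attr(panel, "predictors"), focal_species()))])
  for (sp in attr(enc_sp, "predictors")) {
    expect_equal(enc_sp[[sp]], panel[[sp]])
  }
})
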