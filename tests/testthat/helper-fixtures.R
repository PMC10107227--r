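# Shared fixtures and independent oracles used across the test files.

# Write a scan CSV from a data.frame of character columns and read it back.
write_scan_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

scan_df <- function(date, time, zone, species, count) {
  data.frame(date = date, time = time, zone = zone, species = species,
             count = count, stringsAsFactors = FALSE)
}

# A 4-scan run in zone 1A reproducing the worked joining example:
# RB absent for two scans then arriving (and staying), BH and SC present for
# the first three scans. y_RB = (0,0,1,0); x_BH = x_SC = (0,1,1,0); RB joins
# BH and SC at 05:40.
fig_joining_scans <- function() {
  times <- c("05:30", "05:35", "05:40", "05:45")
  rows <- rbind(
    scan_df("2010-10-22", times[3:4], "1A", "RB", 1),
    scan_df("2010-10-22", times[1:3], "1A", "BH", 2),
    scan_df("2010-10-22", times[1:3], "1A", "SC", 1)
  )
  read_scan_table(write_scan_csv(rows))
}

# Random filtered scan table over a handful of days/zones/species.
random_scan_table <- function(seed = 1, n = 60,
                              dates = as.Date("2010-10-20") + 0:5,
                              times = sprintf("05:%02d", seq(0, 55, 5)),
                              zones = c("1A", "2C", "3B"),
                              species = c("RB", "CF", "BH", "SC")) {
  set.seed(seed)
  df <- data.frame(date = sample(as.character(dates), n, TRUE),
                   time = sample(times, n, TRUE),
                   zone = sample(zones, n, TRUE),
                   species = sample(species, n, TRUE),
                   count = sample(1:5, n, TRUE), stringsAsFactors = FALSE)
  df <- df[!duplicated(df[, 1:4]), ]
  read_scan_table(write_scan_csv(df))
}

# Hand-rolled iteratively reweighted least squares for logistic regression;
# the independent oracle for the zero-variance-limit checks.
irls_logistic <- function(X, y, tol = 1e-10, maxit = 100) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  names(beta) <- c("(Intercept)", colnames(X)[-1])
  beta
}

# Construct a design panel directly (bypassing the scan pipeline) for the
# model-level simulations: binary predictors, random-intercept labels, and a
# response drawn from the logistic model with the given coefficients and
# random-effect standard deviations.
make_model_panel <- function(n = 2000, beta = c(`(Intercept)` = -1),
                             n_predictors = 1,
                             re_sd = c(zone = 0, tod = 0, date = 0),
                             n_levels = c(zone = 6, tod = 10, date = 15),
                             seed = 1) {
  set.seed(seed)
  preds <- paste0("x", seq_len(n_predictors))
  X <- matrix(rbinom(n * n_predictors, 1, 0.3), n, n_predictors,
              dimnames = list(NULL, preds))
  zone <- sample(paste0("z", seq_len(n_levels["zone"])), n, TRUE)
  tod <- sample(paste0("t", seq_len(n_levels["tod"])), n, TRUE)
  date <- sample(paste0("d", seq_len(n_levels["date"])), n, TRUE)
  u <- rnorm(n_levels["zone"], 0, re_sd["zone"])[match(zone, paste0("z", seq_len(n_levels["zone"])))] +
    rnorm(n_levels["tod"], 0, re_sd["tod"])[match(tod, paste0("t", seq_len(n_levels["tod"])))] +
    rnorm(n_levels["date"], 0, re_sd["date"])[match(date, paste0("d", seq_len(n_levels["date"])))]
  b <- rep(0, n_predictors)
  common <- intersect(preds, names(beta))
  b[match(common, preds)] <- beta[common]
  eta <- unname(beta["(Intercept)"]) + drop(X %*% b) + u
  y <- rbinom(n, 1, plogis(eta))
  coforage:::new_design_panel(y = y, X = as.data.frame(X),
                              zone = zone, tod = tod, date = date,
                              focal = "x0", design_kind = "copresence",
                              predictors = preds)
}

# Minimal hand-built fit objects for testing the likelihood-ratio formula.
fake_fit <- function(loglik, k, nobs = 100) {
  structure(list(loglik = loglik, k = k, nobs = nobs), class = "coforage_fit")
}

# Hand-built schema_competition skeleton for the derived summaries.
fake_competition <- function(focal, best, categories, classification) {
  structure(list(focal = focal, best = best,
                 coef_table = data.frame(category = categories,
                                         estimate = NA_real_, se = NA_real_,
                                         p = NA_real_,
                                         classification = classification,
                                         stringsAsFactors = FALSE)),
            class = "schema_competition")
}
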