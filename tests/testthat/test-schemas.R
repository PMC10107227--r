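test_that("schema resolution matches the categorization table", {
  attrs <- species_attributes()
  expect_equal(unname(vapply(schema_names(), schema_n_categories,
                             integer(1))),
               c(12L, 5L, 2L, 3L, 5L, 5L, 3L, 2L, 2L))

  # absolute schemas pull the attribute columns
  clade <- resolve_schema("clade", attrs = attrs)
  expect_equal(unname(clade[c("DH", "WE")]), rep("parakeet", 2))
  expect_equal(unname(clade[c("SC", "BY", "RG")]), rep("large macaw", 3))
  lm <- resolve_schema("large_macaw", attrs = attrs)
  expect_equal(sum(lm == "yes"), 3L)
  expect_equal(unname(resolve_schema("back_colour")[c("SC", "BY", "RG")]),
               c("red", "blue", "red"))
  expect_equal(unname(resolve_schema("size")[c("DH", "RB", "RG")]),
               c("small", "medium", "large"))
  expect_equal(unname(resolve_schema("species")["ME"]), "ME")

  # similar-size neighbours of BH are OC (below) and RB (above)
  sim_bh <- resolve_schema("similar", focal = "BH", attrs = attrs)
  expect_equal(sort(names(sim_bh)[sim_bh == "similar"]), c("OC", "RB"))
  expect_equal(sum(sim_bh == "different"), 9L)

  # larger/smaller split for focal BH
  lg_bh <- resolve_schema("larger", focal = "BH", attrs = attrs)
  expect_setequal(names(lg_bh)[lg_bh == "smaller"], c("DH", "WB", "WE", "OC"))
  expect_setequal(names(lg_bh)[lg_bh == "larger"],
                  c("RB", "CF", "YC", "ME", "SC", "BY", "RG"))

  # boundary species: everything is larger than DH; RG has one size neighbour
  lg_dh <- resolve_schema("larger", focal = "DH", attrs = attrs)
  expect_true(all(lg_dh[setdiff(names(lg_dh), "DH")] == "larger"))
  sim_rg <- resolve_schema("similar", focal = "RG", attrs = attrs)
  expect_equal(names(sim_rg)[sim_rg == "similar"], "BY")

  expect_error(resolve_schema("similar", attrs = attrs), "focal")
  expect_error(resolve_schema("nonsense"), "arg")
})

test_that("usage complexity counts significantly used categories", {
  all_sig <- fake_competition("RB", "back_colour",
                              c("green", "red", "blue"),
                              c("preferred", "preferred", "avoided"))
  expect_equal(usage_complexity(all_sig)$value, 3L)

  one_sig <- fake_competition("RB", "back_colour",
                              c("green", "red", "blue"),
                              c("preferred", "neutral", "neutral"))
  expect_equal(usage_complexity(one_sig)$value, 1L)

  none <- fake_competition("RB", "back_colour", c("green", "red", "blue"),
                           rep("neutral", 3))
  expect_equal(usage_complexity(none)$value, 0L)
})

test_that("category preferences map back onto species identities", {
  # best schema large_macaw with the yes category preferred:
  # all three large macaws are labelled preferred for a non-macaw focal
  res <- fake_competition("BH", "large_macaw", c("no", "yes"),
                          c("neutral", "preferred"))
  pm <- category_preference_map(res)
  expect_true(all(pm$labels[c("SC", "BY", "RG")] == "preferred"))
  expect_true(all(pm$labels[c("DH", "WB", "RB")] == "neutral"))
  # BH's own category (no) is neutral and has other members
  expect_equal(pm$own_category_preference, "neutral")

  # a focal that is the sole member of its category: OC is the only
  # black-headed species, so its own-category preference is undefined
  res_oc <- fake_competition("OC", "head_colour",
                             c("green", "orange", "blue", "red"),
                             c("preferred", "neutral", "neutral", "neutral"))
  pm_oc <- category_preference_map(res_oc)
  expect_true(is.na(pm_oc$own_category_preference))
  expect_true(all(pm_oc$labels[c("DH", "WE", "RB")] == "preferred"))

  # neutral-only result labels all 11 neutral
  res_n <- fake_competition("RB", "size", c("small", "medium", "large"),
                            rep("neutral", 3))
  expect_true(all(category_preference_map(res_n)$labels == "neutral"))
})

test_that("schema competition recovers a planted schema and stays coherent", {
  cfg <- sim_config(n_days = 30, zones = c("1A", "2C"),
                    generating_schema = "size", seed = 5)
  p <- presence_table(filter_scans(simulate_scans(cfg)))
  runs <- segment_runs(p)
  cr <- compete_schemas(p, "DH", runs = runs)

  expect_s3_class(cr, "schema_competition")
  expect_equal(cr$best, "size")
  expect_equal(sum(cr$table$weight, na.rm = TRUE), 1)
  expect_equal(cr$table$schema[which.min(cr$table$aic)], cr$best)
  expect_equal(cr$table$delta[cr$table$schema == cr$best], 0)

  # internal consistency: the species-schema AIC equals the AIC of the raw
  # 11-predictor joining model
  raw <- fit_binomial_glmm(build_join_design(p, "DH", runs))
  expect_equal(cr$table$aic[cr$table$schema == "species"], raw$aic,
               tolerance = 1e-6)

  # all nine models share one row set by construction
  expect_true(all(vapply(cr$fits, function(f) f$nobs, numeric(1)) ==
                    cr$fits$species$nobs))

  # usage complexity is bounded by the encodable categories of the best model
  uc <- usage_complexity(cr)
  expect_lte(uc$value, nrow(cr$coef_table))
  expect_gte(uc$value, 0L)

  # the planted own-size-class preference surfaces in the preference map
  pm <- category_preference_map(cr)
  expect_equal(pm$own_category_preference, "preferred")

  # the optional per-category likelihood-ratio test agrees with Wald on the
  # decisively preferred category
  cr_lrt <- compete_schemas(p, "DH", runs = runs, schemas = "size",
                            category_test = "lrt")
  wald_cls <- cr$coef_table$classification[cr$coef_table$category == "small"]
  lrt_cls <- cr_lrt$coef_table$classification[
    cr_lrt$coef_table$category == "small"]
  expect_equal(lrt_cls, wald_cls)
  expect_equal(lrt_cls, "preferred")
})

test_that("mass-difference edge test matches the exact enumeration", {
  attrs <- species_attributes()
  # craft edges whose mass differences are exactly {1,2,3} affiliative and
  # {4,5,6} avoidant, via mass overrides
  es <- data.frame(
    focal = c("DH", "DH", "DH", "DH", "DH", "DH"),
    predictor = c("WB", "WE", "OC", "BH", "RB", "CF"),
    estimate = c(1, 1, 1, -1, -1, -1),
    p = 0.001, q = 0.01,
    sign = rep(c("affiliative", "avoidant"), each = 3),
    significant = TRUE, converged = TRUE, stringsAsFactors = FALSE)
  class(es) <- c("edge_set", "data.frame")
  masses <- c(WB = 109, WE = 110, OC = 111, BH = 112, RB = 113, CF = 114)
  attrs3 <- species_attributes(masses)
  out <- mass_difference_edge_test(es, attrs3)
  expect_equal(out$U, 9)
  # exact one-tailed p by enumeration over all choose(6,3) group assignments:
  # only the observed split puts every avoidant diff above every affiliative
  diffs <- c(1, 2, 3, 4, 5, 6)
  combs <- combn(6, 3)
  u_obs <- sum(outer(c(4, 5, 6), c(1, 2, 3), ">"))
  u_all <- apply(combs, 2, function(ix) {
    sum(outer(diffs[ix], diffs[-ix], ">"))
  })
  p_exact <- mean(u_all >= u_obs)
  expect_equal(out$p, p_exact)
  expect_equal(out$p, 0.05)
  expect_equal(out$mean_diff_affiliative, 2)
  expect_equal(out$mean_diff_avoidant, 5)

  # identical difference sets in the two groups: one-tailed p = 0.5 exactly
  es3 <- data.frame(
    focal = c("DH", "WE", "BH", "CF"), predictor = c("WB", "OC", "RB", "YC"),
    estimate = c(1, 1, -1, -1), p = 0.001, q = 0.01,
    sign = c("affiliative", "affiliative", "avoidant", "avoidant"),
    significant = TRUE, converged = TRUE, stringsAsFactors = FALSE)
  class(es3) <- c("edge_set", "data.frame")
  attrs5 <- species_attributes(c(WB = 118, WE = 130, OC = 150,
                                 BH = 234, RB = 244, CF = 360, YC = 380))
  # diffs: affiliative {10, 20}, avoidant {10, 20}
  out3 <- mass_difference_edge_test(es3, attrs5)
  expect_equal(out3$p, 0.5)

  # one empty group: test NA, means still reported
  es_aff <- es[es$sign == "affiliative", ]
  class(es_aff) <- c("edge_set", "data.frame")
  out4 <- mass_difference_edge_test(es_aff, attrs3)
  expect_true(is.na(out4$p))
  expect_equal(out4$mean_diff_affiliative, 2)
  expect_true(is.na(out4$mean_diff_avoidant))

  # construction: signs assigned by thresholding the mass difference give a
  # decisive one-tailed result at 20+ edges per group
  set.seed(41)
  sp <- focal_species()
  pairs <- expand.grid(focal = sp, predictor = sp,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$focal != pairs$predictor, ]
  mass <- setNames(attrs$mass_g, attrs$code)
  d <- abs(mass[pairs$focal] - mass[pairs$predictor])
  pairs$sign <- ifelse(d > stats::median(d), "avoidant", "affiliative")
  pairs$estimate <- ifelse(pairs$sign == "affiliative", 1, -1)
  pairs$p <- 0.001; pairs$q <- 0.01
  pairs$significant <- TRUE; pairs$converged <- TRUE
  class(pairs) <- c("edge_set", "data.frame")
  out5 <- mass_difference_edge_test(pairs, attrs)
  expect_lt(out5$p, 0.01)
})

test_that("complexity-centrality regression is plain OLS", {
  sp <- focal_species()
  cs <- data.frame(species = sp, degree = 0:11, betweenness = rep(2, 12))
  uc <- data.frame(species = sp, value = 2 * (0:11))
  expect_message(out <- suppressWarnings(
    complexity_centrality_regression(uc, cs)), "zero variance")
  expect_equal(out$estimate[out$measure == "degree"], 2, tolerance = 1e-12)
  expect_lt(out$p[out$measure == "degree"], 1e-10)
  # zero-variance regressor: NA with a message
  expect_true(is.na(out$estimate[out$measure == "betweenness"]))

  # constant response: slope 0
  uc0 <- data.frame(species = sp, value = rep(3, 12))
  out0 <- suppressWarnings(suppressMessages(
    complexity_centrality_regression(uc0, cs)))
  expect_equal(out0$estimate[out0$measure == "degree"], 0, tolerance = 1e-12)

  # sampling check: known slope 0.2, noise sd 0.5, n = 12
  set.seed(19)
  x <- 0:11
  y <- 0.2 * x + rnorm(12, 0, 0.5)
  cs2 <- data.frame(species = sp, degree = x, betweenness = x)
  uc2 <- data.frame(species = sp, value = y)
  out2 <- complexity_centrality_regression(uc2, cs2)
  est <- out2$estimate[out2$measure == "degree"]
  se <- out2$se[out2$measure == "degree"]
  expect_lt(abs(est - 0.2), 3 * se)
})
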