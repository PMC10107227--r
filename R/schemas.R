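## Categorization-schema definitions and competition: nine ways of grouping
## the 12 species (from full species identity down to two-category systems),
## competed per focal species by AIC on the joining model, plus the derived
## usage-complexity measure, the preference map, and the two cross-cutting
## statistical checks (mass-difference edge test, complexity ~ centrality
## regression).

CO_SCHEMAS <- c("species", "clade", "large_macaw", "back_colour",
                "head_colour", "face_colour", "size", "larger", "similar")

#' Names of the nine categorization schemas
#'
#' Absolute schemas map each species to a fixed category (species identity,
#' clade/shape, large-macaw flag, back/head/face colour, size class); the two
#' relative schemas (`larger`, `similar`) are resolved per focal species from
#' mean body mass.
#'
#' @return character vector of schema names.
#' @export
schema_names <- function() CO_SCHEMAS

## Canonical category orderings, used for stable predictor column order.
schema_category_levels <- function(schema, attrs = species_attributes()) {
  switch(schema,
    species = attrs$code[order(attrs$mass_g)],
    clade = c("parakeet", "small parrot", "large parrot", "small macaw",
              "large macaw"),
    large_macaw = c("no", "yes"),
    back_colour = c("green", "red", "blue"),
    head_colour = c("green", "orange", "black", "blue", "red"),
    face_colour = c("green-grey", "orange", "yellow", "blue", "white"),
    size = c("small", "medium", "large"),
    larger = c("smaller", "larger"),
    similar = c("similar", "different"),
    stop("unknown schema: ", schema))
}

#' Number of categories per schema
#'
#' @param schema schema name.
#' @param attrs species-attribute table.
#' @return integer count of categories (12, 5, 2, 3, 5, 5, 3, 2, 2 for the
#'   nine schemas in [schema_names()] order).
#' @export
schema_n_categories <- function(schema, attrs = species_attributes()) {
  length(schema_category_levels(schema, attrs))
}

#' Resolve a schema to a concrete species-to-category mapping
#'
#' Absolute schemas return the corresponding attribute column. The relative
#' schemas need a focal species: `larger` labels every other species
#' `"larger"` or `"smaller"` by mean mass relative to the focal; `similar`
#' labels the species immediately adjacent in the mass ranking (one below and
#' one above; boundary species have a single neighbour) `"similar"` and all
#' others `"different"`. The focal itself is labelled `"(focal)"` under the
#' relative schemas and is in any case excluded from its own category when
#' predictors are encoded.
#'
#' @param schema schema name.
#' @param focal focal species code (required for `larger` and `similar`).
#' @param attrs species-attribute table.
#' @return named character vector mapping all 12 species codes to categories.
#' @export
resolve_schema <- function(schema, focal = NULL,
                           attrs = species_attributes()) {
  schema <- match.arg(schema, CO_SCHEMAS)
  codes <- attrs$code
  if (schema %in% c("larger", "similar")) {
    if (is.null(focal) || !focal %in% codes) {
      stop("relative schema '", schema, "' needs a valid focal species")
    }
    mass <- stats::setNames(attrs$mass_g, codes)
    map <- stats::setNames(rep(NA_character_, length(codes)), codes)
    if (schema == "larger") {
      map[] <- ifelse(mass > mass[focal], "larger", "smaller")
    } else {
      ranked <- codes[order(mass)]
      i <- match(focal, ranked)
      neigh <- ranked[c(i - 1L, i + 1L)]
      neigh <- neigh[!is.na(neigh)]
      map[] <- ifelse(codes %in% neigh, "similar", "different")
    }
    map[focal] <- "(focal)"
    return(map)
  }
  col <- switch(schema,
    species = codes,
    clade = attrs$clade,
    large_macaw = ifelse(attrs$large_macaw, "yes", "no"),
    back_colour = attrs$back_colour,
    head_colour = attrs$head_colour,
    face_colour = attrs$face_colour,
    size = attrs$size_class)
  stats::setNames(as.character(col), codes)
}

#' Compete the nine categorization schemas for one focal species
#'
#' Builds the joining design panel for the focal, re-encodes its predictors
#' under each schema, fits each encoding with the binomial mixed model (all
#' nine models therefore share an identical row set), and compares the fits
#' by AIC. Akaike differences and weights are computed over the converged
#' fits. The best (minimum-AIC) model is flagged "strongly differentiated"
#' when the runner-up's Akaike difference exceeds 2, and the runner-up is
#' always reported alongside. Each category coefficient of the best model is
#' classified as preferred (Wald p < `alpha`, positive estimate), avoided
#' (significant, negative) or neutral.
#'
#' @param p a `presence_table`.
#' @param focal focal species code.
#' @param attrs species-attribute table.
#' @param alpha per-category significance level in the best model.
#' @param runs optional precomputed `run_table`.
#' @param schemas schema names to compete (default all nine).
#' @param category_test how per-category significance in the best model is
#'   assessed: `"wald"` (default) uses the coefficient z-test; `"lrt"`
#'   refits the best model dropping each category in turn.
#' @param constrain_zero_variance passed to [fit_binomial_glmm()].
#' @return a `schema_competition`: list with `focal`, `table` (per schema:
#'   `schema`, `n_categories`, `k`, `aic`, `delta`, `weight`, `converged`),
#'   `best`, `runner_up`, `strongly_differentiated`, `coef_table` (per
#'   category of the best model: `category`, `estimate`, `se`, `p`,
#'   `classification`), and `fits` (the `coforage_fit` objects).
#' @export
compete_schemas <- function(p, focal, attrs = species_attributes(),
                            alpha = 0.05, runs = NULL,
                            schemas = schema_names(),
                            category_test = c("wald", "lrt"),
                            constrain_zero_variance = FALSE) {
  stopifnot(inherits(p, "presence_table"))
  category_test <- match.arg(category_test)
  if (is.null(runs)) runs <- segment_runs(p)
  panel <- build_join_design(p, focal, runs = runs)
  encoded <- list()
  fits <- list()
  tab <- data.frame(schema = schemas, n_categories = NA_integer_,
                    k = NA_integer_, aic = NA_real_, converged = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(schemas)) {
    enc <- encode_schema_predictors(panel, schemas[i], attrs = attrs)
    encoded[[schemas[i]]] <- enc
    fit <- fit_binomial_glmm(enc,
                             constrain_zero_variance = constrain_zero_variance)
    fits[[schemas[i]]] <- fit
    tab$n_categories[i] <- length(attr(enc, "predictors"))
    tab$k[i] <- fit$k
    tab$aic[i] <- if (fit$converged) fit$aic else NA_real_
    tab$converged[i] <- fit$converged
  }
  aw <- akaike_weights(stats::setNames(tab$aic, tab$schema))
  tab$delta <- as.numeric(aw$delta)
  tab$weight <- as.numeric(aw$weight)
  ord <- order(tab$aic)
  best <- tab$schema[ord[1L]]
  runner_up <- if (length(ord) > 1L) tab$schema[ord[2L]] else NA_character_
  strongly <- if (is.na(runner_up)) NA else tab$delta[ord[2L]] > 2

  bf <- fits[[best]]
  cats <- bf$predictors
  p_cat <- as.numeric(bf$p_wald[cats])
  if (category_test == "lrt") {
    for (j in seq_along(cats)) {
      red <- fit_binomial_glmm(encoded[[best]], setdiff(cats, cats[j]),
                               constrain_zero_variance =
                                 constrain_zero_variance)
      p_cat[j] <- lrt_compare(bf, red)$p
    }
  }
  classification <- rep("neutral", length(cats))
  sig <- !is.na(p_cat) & p_cat < alpha
  classification[sig & bf$estimates[cats] > 0] <- "preferred"
  classification[sig & bf$estimates[cats] < 0] <- "avoided"
  coef_table <- data.frame(category = cats,
                           estimate = as.numeric(bf$estimates[cats]),
                           se = as.numeric(bf$se[cats]),
                           p = p_cat,
                           classification = classification,
                           stringsAsFactors = FALSE)
  out <- list(focal = focal,
              table = tab[, c("schema", "n_categories", "k", "aic", "delta",
                              "weight", "converged")],
              best = best, runner_up = runner_up,
              strongly_differentiated = strongly,
              coef_table = coef_table, alpha = alpha, fits = fits)
  class(out) <- "schema_competition"
  out
}

#' @export
print.schema_competition <- function(x, ...) {
  cat(sprintf("<schema_competition> focal %s: best = %s (runner-up %s%s)\n",
              x$focal, x$best, x$runner_up,
              if (isTRUE(x$strongly_differentiated))
                ", strongly differentiated" else ""))
  tab <- x$table[order(x$table$aic), ]
  print(tab, digits = 4, row.names = FALSE)
  cat("categories of the best model:\n")
  print(x$coef_table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Usage complexity of a schema competition result
#'
#' The number of categories in the focal's best-fit schema that the species
#' significantly preferred or avoided.
#'
#' @param result a `schema_competition`.
#' @return a list with `focal`, `best_schema` and integer `value`.
#' @export
usage_complexity <- function(result) {
  stopifnot(inherits(result, "schema_competition"))
  list(focal = result$focal, best_schema = result$best,
       value = sum(result$coef_table$classification %in%
                     c("preferred", "avoided")))
}

#' Map best-model category preferences back onto species identities
#'
#' Labels each of the 11 non-focal species preferred, avoided or neutral
#' according to the classification of the category it falls into under the
#' focal's best-fit schema. Categories that could not be encoded or estimated
#' yield NA labels. Also reports whether the focal's own category was
#' preferred (the similarity-preference summary): NA when the focal is the
#' sole member of its category (no joinable same-category partner exists) or
#' when the best schema defines no own category for the focal (the `larger`
#' schema).
#'
#' @param result a `schema_competition`.
#' @param attrs species-attribute table.
#' @return a list with `labels` (named character vector over the 11 other
#'   species) and `own_category_preference` (`"preferred"`, `"avoided"`,
#'   `"neutral"` or NA).
#' @export
category_preference_map <- function(result, attrs = species_attributes()) {
  stopifnot(inherits(result, "schema_competition"))
  focal <- result$focal
  schema <- result$best
  mapping <- resolve_schema(schema, focal = focal, attrs = attrs)
  others <- setdiff(names(mapping), focal)
  cls <- stats::setNames(result$coef_table$classification,
                         result$coef_table$category)
  cat_key <- function(cat) if (schema == "species") cat else sanitize_names(cat)
  labels <- stats::setNames(rep(NA_character_, length(others)), others)
  for (sp in others) {
    key <- cat_key(mapping[sp])
    if (key %in% names(cls)) labels[sp] <- cls[[key]]
  }
  own_cat <- switch(schema,
                    larger = NA_character_,
                    similar = "similar",
                    unname(mapping[focal]))
  own <- NA_character_
  if (!is.na(own_cat)) {
    has_partner <- any(mapping[others] == own_cat)
    key <- cat_key(own_cat)
    if (has_partner && key %in% names(cls)) own <- cls[[key]]
  }
  list(labels = labels, own_category_preference = own)
}

#' One-tailed mass-difference test between edge types
#'
#' For every significant edge, takes the absolute difference in mean body
#' mass between the two species, and tests with a one-tailed Mann-Whitney U
#' test whether avoidant edges carry larger mass differences than affiliative
#' ones. The U statistic reported is for the avoidant group.
#'
#' @param edges an `edge_set`.
#' @param attrs species-attribute table.
#' @return a list with `mean_diff_affiliative`, `mean_diff_avoidant` (grams),
#'   `n_affiliative`, `n_avoidant`, `U` and one-tailed `p` (NA when either
#'   group is empty; group means are still reported).
#' @export
mass_difference_edge_test <- function(edges, attrs = species_attributes()) {
  stopifnot(inherits(edges, "edge_set"))
  mass <- stats::setNames(attrs$mass_g, attrs$code)
  sig <- edges[edges$significant, , drop = FALSE]
  diffs <- abs(mass[sig$focal] - mass[sig$predictor])
  aff <- diffs[sig$sign == "affiliative"]
  avo <- diffs[sig$sign == "avoidant"]
  out <- list(mean_diff_affiliative = if (length(aff)) mean(aff) else NA_real_,
              mean_diff_avoidant = if (length(avo)) mean(avo) else NA_real_,
              n_affiliative = length(aff), n_avoidant = length(avo),
              U = NA_real_, p = NA_real_)
  if (length(aff) > 0 && length(avo) > 0) {
    # exact when sample sizes allow; normal approximation without continuity
    # correction otherwise, so a fully symmetric case gives p = 0.5 exactly
    wt <- suppressWarnings(
      stats::wilcox.test(avo, aff, alternative = "greater", correct = FALSE))
    out$U <- unname(wt$statistic)
    out$p <- wt$p.value
  }
  out
}

#' Regress usage complexity on network centrality
#'
#' Ordinary least squares of per-species usage complexity on degree
#' centrality and, separately, on betweenness centrality.
#'
#' @param uc a `data.frame` with columns `species` and `value` (usage
#'   complexity), e.g. built from [usage_complexity()] results.
#' @param cs centrality scores from [centrality_scores()].
#' @return a `data.frame` with one row per centrality measure: `measure`,
#'   `estimate`, `se`, `t`, `p`, `n`. A zero-variance regressor yields an NA
#'   row with a message.
#' @export
complexity_centrality_regression <- function(uc, cs) {
  dat <- merge(uc, cs, by = "species")
  one <- function(measure) {
    x <- dat[[measure]]
    if (length(unique(x)) < 2L) {
      message("regressor '", measure, "' has zero variance; slope undefined")
      return(data.frame(measure = measure, estimate = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_, n = nrow(dat)))
    }
    fit <- stats::lm(dat$value ~ x)
    co <- summary(fit)$coefficients
    if (nrow(co) < 2L) {  # perfectly constant response: slope 0, no test
      return(data.frame(measure = measure, estimate = 0, se = NA_real_,
                        t = NA_real_, p = NA_real_, n = nrow(dat)))
    }
    data.frame(measure = measure, estimate = co[2, 1], se = co[2, 2],
               t = co[2, 3], p = co[2, 4], n = nrow(dat),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("degree"), one("betweenness"))
  rownames(out) <- NULL
  out
}
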