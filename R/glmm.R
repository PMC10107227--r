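## Binomial mixed-model fitting, likelihood-ratio model comparison, FDR
## adjustment, Akaike weights, and directed signed edge inference.
##
## The model for every design panel is a logit-link Bernoulli regression with
## additive 0/1 fixed effects and crossed random intercepts for zone,
## time-of-morning and date, fitted by maximizing the Laplace-approximated
## marginal likelihood (lme4::glmer). Variance components may be constrained
## to zero, in which case the marginal likelihood reduces exactly to the
## ordinary Bernoulli likelihood and the fit is plain logistic regression.

## bobyqa converges to the same optimum as the default optimizer on these
## sparse binary designs in a fraction of the time.
glmm_control <- function() {
  lme4::glmerControl(optimizer = "bobyqa",
                     calc.derivs = FALSE,
                     check.conv.singular = "ignore")
}

#' Fit a binomial GLMM with crossed random intercepts to a design panel
#'
#' Fixed effects are an intercept plus the requested 0/1 predictor columns;
#' random intercepts are crossed over the panel's `zone`, `tod` and `date`
#' labels. Predictor columns that are constant in the panel carry no
#' information and are dropped (recorded in `$dropped`). Fits whose optimizer
#' failed or whose coefficients indicate complete separation are flagged as
#' non-converged.
#'
#' @param panel a `design_panel`.
#' @param predictors character vector of predictor column names; default all
#'   of `attr(panel, "predictors")`. May be empty (intercept-only model).
#' @param constrain_zero_variance if TRUE, the three random-intercept
#'   variances are fixed at zero; the resulting marginal likelihood is the
#'   plain Bernoulli likelihood, maximized by iteratively reweighted least
#'   squares (`stats::glm`).
#' @return a `coforage_fit`: list with `estimates`, `se`, `z`, `p_wald`
#'   (named by predictor, intercept included), `loglik`, `k` (parameter
#'   count: fixed effects plus estimated variance components), `aic`,
#'   `nobs`, `converged`, `messages`, `dropped`, `predictors`, `engine`
#'   and the underlying `model` object.
#' @export
fit_binomial_glmm <- function(panel, predictors = NULL,
                              constrain_zero_variance = FALSE) {
  stopifnot(inherits(panel, "design_panel"))
  if (is.null(predictors)) predictors <- attr(panel, "predictors")
  stopifnot(all(predictors %in% names(panel)))
  if (isTRUE(attr(panel, "degenerate"))) {
    stop("panel response is constant; the model is degenerate")
  }
  dat <- as.data.frame(panel)
  keep <- vapply(predictors,
                 function(v) length(unique(dat[[v]])) > 1L, logical(1))
  dropped <- predictors[!keep]
  predictors <- predictors[keep]
  rhs <- if (length(predictors) > 0) {
    paste(sprintf("`%s`", predictors), collapse = " + ")
  } else "1"
  msgs <- character()
  collect <- function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  if (constrain_zero_variance) {
    form <- stats::as.formula(paste("y ~", rhs))
    model <- withCallingHandlers(
      stats::glm(form, family = stats::binomial(), data = dat),
      warning = collect)
    ll <- as.numeric(stats::logLik(model))
    k <- attr(stats::logLik(model), "df")
    est <- stats::coef(model)
    se <- sqrt(diag(stats::vcov(model)))
    converged <- isTRUE(model$converged)
    engine <- "glm (variances fixed at 0)"
  } else {
    re_factors <- c("zone", "tod", "date")
    re_ok <- vapply(re_factors, function(v) nlevels(droplevels(dat[[v]])) > 1L,
                    logical(1))
    if (!any(re_ok)) {
      stop("no random-intercept factor has more than one level; ",
           "use constrain_zero_variance = TRUE for a fixed-effects fit")
    }
    if (!all(re_ok)) {
      msgs <- c(msgs, paste("random intercept(s) dropped (single level):",
                            paste(re_factors[!re_ok], collapse = ", ")))
    }
    re_terms <- paste(sprintf("(1 | %s)", re_factors[re_ok]), collapse = " + ")
    form <- stats::as.formula(paste("y ~", rhs, "+", re_terms))
    model <- withCallingHandlers(
      lme4::glmer(form, family = stats::binomial(), data = dat,
                  control = glmm_control()),
      warning = collect)
    ll <- as.numeric(stats::logLik(model))
    k <- attr(stats::logLik(model), "df")
    est <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    opt_ok <- isTRUE(model@optinfo$conv$opt == 0L)
    lme4_msgs <- unlist(model@optinfo$conv$lme4$messages)
    fatal <- any(grepl("failed to converge", c(msgs, lme4_msgs),
                       ignore.case = TRUE))
    converged <- opt_ok && !fatal
    engine <- "glmer (Laplace)"
  }
  names(est) <- gsub("`", "", names(est))
  names(se) <- names(est)
  separated <- any(abs(est[names(est) != "(Intercept)"]) > 15) ||
    any(!is.finite(se))
  z <- est / se
  fit <- list(estimates = est, se = se, z = z,
              p_wald = 2 * stats::pnorm(-abs(z)),
              loglik = ll, k = k, aic = -2 * ll + 2 * k,
              nobs = nrow(dat),
              converged = converged && !separated,
              separated = separated,
              messages = msgs,
              dropped = dropped, predictors = predictors,
              engine = engine, model = model)
  class(fit) <- "coforage_fit"
  fit
}

#' @export
print.coforage_fit <- function(x, ...) {
  cat(sprintf("<coforage_fit> %s: %d obs, %d predictors, AIC %.2f%s\n",
              x$engine, x$nobs, length(x$predictors), x$aic,
              if (!x$converged) " [not converged]" else ""))
  print(round(cbind(estimate = x$estimates, se = x$se, p = x$p_wald), 4))
  invisible(x)
}

#' Likelihood-ratio comparison of nested fits
#'
#' Computes the deviance `D = 2 (loglik_full - loglik_reduced)` and its
#' upper-tail chi-square p-value with degrees of freedom equal to the
#' difference in parameter counts (1 for a single dropped predictor).
#' Identical models give D = 0 and p = 1. A deviance below `-tol` indicates
#' the reduced model out-fitted the full one (an optimizer failure) and
#' raises a warning; small negative deviances are clamped to zero.
#'
#' @param full,reduced `coforage_fit` objects on the same panel, the reduced
#'   model's predictors a subset of the full model's.
#' @param tol tolerance for negative deviances.
#' @return a list with `deviance`, `df` and `p`.
#' @export
lrt_compare <- function(full, reduced, tol = 1e-6) {
  stopifnot(inherits(full, "coforage_fit"), inherits(reduced, "coforage_fit"))
  if (full$nobs != reduced$nobs) {
    stop("models were fitted to different numbers of observations")
  }
  df <- full$k - reduced$k
  D <- 2 * (full$loglik - reduced$loglik)
  if (D < -tol) {
    warning(sprintf("negative deviance (%.3g): full model fit worse than %s",
                    D, "reduced; refit advised"))
  }
  D <- max(D, 0)
  p <- if (df <= 0L) {
    1
  } else {
    stats::pchisq(D, df = df, lower.tail = FALSE)
  }
  list(deviance = D, df = df, p = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted values `q_i = min over j with p_(j) >= p_(i) of
#' m p_(j) / rank(j)`, capped at 1; order-preserving in the raw p-values.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs passed through).
#' @return numeric vector of adjusted q-values.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  stats::p.adjust(pvals, method = "BH")
}

#' Akaike differences and weights
#'
#' `delta_i = aic_i - min(aic)`; `w_i = exp(-delta_i / 2)` normalized to sum
#' to one over the finite entries. Non-finite AICs (non-converged fits) get
#' NA weight and are excluded from the normalization.
#'
#' @param aics numeric vector of AIC values (NA allowed).
#' @return list with `delta` and `weight`, same length and names as `aics`.
#' @export
akaike_weights <- function(aics) {
  ok <- is.finite(aics)
  if (!any(ok)) stop("at least one finite AIC is required")
  delta <- aics - min(aics[ok])
  w <- rep(NA_real_, length(aics))
  ew <- exp(-delta[ok] / 2)
  w[ok] <- ew / sum(ew)
  names(delta) <- names(w) <- names(aics)
  list(delta = delta, weight = w)
}

#' Infer the directed signed association network
#'
#' For each focal species a full model (all 11 partner predictors) is
#' compared, by likelihood-ratio test, with 11 reduced models each omitting
#' one predictor. The resulting p-values (132 for a 12-species design) are
#' adjusted jointly by Benjamini-Hochberg; an edge focal -> predictor is
#' retained iff its adjusted value falls below `alpha`, and is signed
#' affiliative (positive coefficient) or avoidant (negative). Degenerate
#' focal panels and non-converged fits yield NA p-values, are excluded from
#' the adjustment family, and are reported in the output.
#'
#' @param p a `presence_table`.
#' @param design_kind `"copresence"` (presence/absence per zone-scan) or
#'   `"joining"` (joining indicator over runs).
#' @param alpha FDR level for calling edges (default 0.05).
#' @param attrs species-attribute table (defines the focal set).
#' @param constrain_zero_variance passed to [fit_binomial_glmm()].
#' @param runs optional precomputed `run_table` (joining designs only).
#' @param verbose print progress per focal.
#' @return an `edge_set`: a `data.frame` with one row per ordered (focal,
#'   predictor) pair and columns `focal`, `predictor`, `estimate`, `p`, `q`,
#'   `sign` (`"affiliative"`/`"avoidant"`), `significant`, `converged`;
#'   attributes `m_tests` (size of the adjustment family), `alpha` and
#'   `design_kind`.
#' @export
infer_edge_network <- function(p, design_kind = c("copresence", "joining"),
                               alpha = 0.05, attrs = species_attributes(),
                               constrain_zero_variance = FALSE,
                               runs = NULL, verbose = FALSE) {
  design_kind <- match.arg(design_kind)
  stopifnot(inherits(p, "presence_table"))
  species <- p$species
  if (design_kind == "joining" && is.null(runs)) runs <- segment_runs(p)
  rows <- list()
  for (focal in species) {
    others <- setdiff(species, focal)
    panel <- if (design_kind == "copresence") {
      build_copresence_design(p, focal)
    } else {
      build_join_design(p, focal, runs = runs)
    }
    if (isTRUE(attr(panel, "degenerate"))) {
      rows[[focal]] <- data.frame(focal = focal, predictor = others,
                                  estimate = NA_real_, p = NA_real_,
                                  converged = FALSE,
                                  stringsAsFactors = FALSE)
      next
    }
    if (verbose) message("fitting focal ", focal)
    full <- fit_binomial_glmm(panel,
                              constrain_zero_variance = constrain_zero_variance)
    pv <- est <- stats::setNames(rep(NA_real_, length(others)), others)
    conv <- stats::setNames(rep(FALSE, length(others)), others)
    for (b in others) {
      if (b %in% full$dropped) next  # constant predictor: no test possible
      reduced <- fit_binomial_glmm(panel, setdiff(attr(panel, "predictors"), b),
                                   constrain_zero_variance =
                                     constrain_zero_variance)
      conv[b] <- full$converged && reduced$converged
      if (conv[b]) {
        pv[b] <- lrt_compare(full, reduced)$p
        est[b] <- full$estimates[b]
      }
    }
    rows[[focal]] <- data.frame(focal = focal, predictor = others,
                                estimate = est, p = pv, converged = conv,
                                stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows)
  rownames(edges) <- NULL
  edges$q <- bh_adjust(edges$p)
  edges$sign <- ifelse(edges$estimate > 0, "affiliative", "avoidant")
  edges$significant <- !is.na(edges$q) & edges$q < alpha
  edges <- edges[, c("focal", "predictor", "estimate", "p", "q", "sign",
                     "significant", "converged")]
  attr(edges, "m_tests") <- sum(!is.na(edges$p))
  attr(edges, "alpha") <- alpha
  attr(edges, "design_kind") <- design_kind
  class(edges) <- c("edge_set", "data.frame")
  edges
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set> %s: %d tests (family m = %d), %d significant at FDR %.2f\n",
              attr(x, "design_kind"), nrow(x), attr(x, "m_tests"),
              sum(x$significant), attr(x, "alpha")))
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig) > 0) print(as.data.frame(sig), digits = 3)
  invisible(x)
}
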