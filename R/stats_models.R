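# Statistical models on the composition table: taxonomic mixed-effects
# regressions (lme4/lmerTest), likelihood-ratio model comparison, Tukey HSD
# contrasts (multcomp), phylogenetic GLS with Pagel's lambda (nlme + ape),
# and the Wilcoxon rank-sum comparison of core-genome fractions.

.region_levels <- c("accessory", "whole", "core")

#' Fit a taxonomic mixed-effects model on the composition table
#'
#' Fits \eqn{y = \beta_0 + \beta_1 x + Z u + \epsilon} by REML, where the
#' response is one of the composition statistics (GC content, GCVAR or
#' relative entropy), the fixed effect is either the region factor
#' (accessory / whole / core, reference level accessory) or GC content, and
#' the random effects are intercepts for the requested taxonomic levels
#' (default genus and species). The observation unit is one row per strain
#' and region. Coefficient p-values use Satterthwaite denominator degrees
#' of freedom. Rows with a missing or `-Inf` response (e.g. zero-deviation
#' GCVAR) are dropped listwise and counted.
#'
#' @param data Composition table joined with strain metadata: must contain
#'   the response column, the fixed-effect column, and the random-level
#'   columns (`species`, `genus`, `phylum` as needed).
#' @param response `"gc"`, `"gcvar"` or `"rel_entropy"`.
#' @param fixed `"region"` or `"gc"`.
#' @param random Character vector of taxonomic random-intercept levels,
#'   ordered coarse to fine; default `c("genus", "species")`.
#' @param gc_percent If `TRUE` (default) GC is modelled in percentage
#'   points (0-100) rather than as a fraction, for readable coefficients.
#' @return A `pancomp_mixed` object: list with the `lmerTest` fit,
#'   coefficient table (`beta`, `se`, `df`, `p`), `var_components`,
#'   `loglik`, `n_obs`, `n_dropped` and a `singular` flag.
#' @export
fit_mixed_model <- function(data,
                            response = c("gc", "gcvar", "rel_entropy"),
                            fixed = c("region", "gc"),
                            random = c("genus", "species"),
                            gc_percent = TRUE) {
  response <- match.arg(response)
  fixed <- match.arg(fixed)
  if (fixed == "gc" && response == "gc") {
    stop("GC content cannot be both response and fixed effect")
  }
  stopifnot(length(random) >= 1L,
            all(random %in% c("phylum", "genus", "species")))
  need <- unique(c(response, fixed, random))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(data)
  keep <- is.finite(df[[response]]) &
    (fixed != "gc" | is.finite(df[["gc"]]))
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("fit_mixed_model: dropping ", n_dropped,
            " row(s) with missing or infinite values")
  }
  df <- df[keep, , drop = FALSE]
  if (gc_percent && "gc" %in% need && max(df$gc, na.rm = TRUE) <= 1) {
    df$gc <- 100 * df$gc
  }
  if (fixed == "region") {
    df$region <- factor(df$region, levels = .region_levels)
    df <- droplevels(df)
    if (nlevels(df$region) < 2L) stop("need at least 2 region levels")
  }
  for (r in random) {
    df[[r]] <- factor(df[[r]])
    if (nlevels(df[[r]]) < 2L) {
      stop("random level '", r, "' has fewer than 2 groups")
    }
  }
  form <- stats::as.formula(paste(
    response, "~", fixed,
    paste(sprintf("+ (1 | %s)", random), collapse = " ")
  ))
  fit <- lmerTest::lmer(form, data = df, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    message("fit_mixed_model: singular fit (a variance component is zero)")
  }
  coefs <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_components <- stats::setNames(vc$vcov, vc$grp)
  structure(
    list(fit = fit, formula = form, data = df,
         beta = coefs[, "Estimate"], se = coefs[, "Std. Error"],
         df = coefs[, "df"], p = coefs[, "Pr(>|t|)"],
         var_components = var_components,
         loglik = as.numeric(stats::logLik(fit)),
         n_obs = nrow(df), n_dropped = n_dropped, singular = singular,
         response = response, fixed = fixed, random = random),
    class = "pancomp_mixed"
  )
}

#' @method print pancomp_mixed
#' @export
print.pancomp_mixed <- function(x, ...) {
  cat("Mixed model:", deparse(x$formula), "\n")
  cat("REML fit on", x$n_obs, "rows (", x$n_dropped, "dropped )\n")
  print(round(cbind(beta = x$beta, se = x$se, df = x$df, p = x$p), 4))
  cat("Random-effect variances:\n")
  print(round(x$var_components, 6))
  if (x$singular) cat("NOTE: singular fit\n")
  invisible(x)
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' Refits both models by maximum likelihood and compares
#' \eqn{2\Delta\log L} to a chi-squared distribution with degrees of
#' freedom equal to the difference in parameter count. The reduced model's
#' random-effect structure must be nested in the full model's. With zero
#' degrees of freedom (identical specifications) the p-value is 1. Note
#' that for a variance component tested on its boundary the chi-squared
#' reference is conservative.
#'
#' @param full,reduced `pancomp_mixed` objects from [fit_mixed_model()].
#' @return List with `statistic`, `df` and `p_value`.
#' @export
lrt_compare <- function(full, reduced) {
  stopifnot(inherits(full, "pancomp_mixed"), inherits(reduced, "pancomp_mixed"))
  if (!all(reduced$random %in% full$random) || reduced$fixed != full$fixed ||
      reduced$response != full$response) {
    stop("models are not nested (random effects, fixed effect and response ",
         "of the reduced model must be contained in the full model)")
  }
  ml_full <- .refit_ml(full)
  ml_red <- .refit_ml(reduced)
  df_full <- attr(stats::logLik(ml_full), "df")
  df_red <- attr(stats::logLik(ml_red), "df")
  if (df_red > df_full) stop("reduced model has more parameters than full model")
  df <- df_full - df_red
  stat <- 2 * (as.numeric(stats::logLik(ml_full)) -
                 as.numeric(stats::logLik(ml_red)))
  if (stat < -1e-6) {
    warning("negative LRT statistic (", format(stat),
            "): optimizer noise beyond tolerance")
  }
  stat <- max(stat, 0)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

.refit_ml <- function(m) {
  if (length(lme4::findbars(m$formula))) {
    lmerTest::lmer(m$formula, data = m$data, REML = FALSE)
  } else {
    stats::lm(m$formula, data = m$data)
  }
}

#' Tukey HSD contrasts among region levels
#'
#' All pairwise contrasts among the modelled region levels with single-step
#' (Tukey) family-wise adjusted p-values, computed with `multcomp::glht` on
#' the mixed-model fit.
#'
#' @param model A `pancomp_mixed` fitted with `fixed = "region"`.
#' @return Tibble with one row per pair: `contrast`, `estimate`, `se`,
#'   `statistic`, `p_unadjusted`, `p_adjusted`.
#' @export
tukey_hsd <- function(model) {
  stopifnot(inherits(model, "pancomp_mixed"))
  if (model$fixed != "region") stop("model was not fitted with fixed = 'region'")
  glht <- multcomp::glht(model$fit, linfct = multcomp::mcp(region = "Tukey"))
  adj <- summary(glht, test = multcomp::adjusted("single-step"))$test
  raw <- summary(glht, test = multcomp::adjusted("none"))$test
  tibble::tibble(
    contrast = names(adj$coefficients),
    estimate = as.numeric(adj$coefficients),
    se = as.numeric(adj$sigma),
    statistic = as.numeric(adj$tstat),
    p_unadjusted = as.numeric(raw$pvalues),
    p_adjusted = as.numeric(adj$pvalues)
  )
}

#' Phylogenetic GLS of a species-level statistic on phylum
#'
#' Generalized least squares with Brownian-motion covariance from the tree,
#' off-diagonal entries scaled by Pagel's lambda. Lambda is estimated by
#' maximum likelihood on [0, 1] (profile over `nlme::gls` fits with
#' `ape::corPagel`); at lambda = 0 the fit reduces to ordinary least
#' squares. The phylum effect is tested with an ANOVA F-test (sequential
#' sums of squares; with a single predictor this equals the marginal test).
#'
#' @param species_table One row per species with at least the columns
#'   `species`, the response, and the predictor.
#' @param tree `ape::phylo` tree whose tip labels match `species_table$species`
#'   one to one, with branch lengths.
#' @param response Response column name (default `"gc"`).
#' @param predictor Explanatory column name (default `"phylum"`).
#' @param lambda Fix lambda at a value in [0, 1] instead of estimating it.
#' @param gc_percent Model GC in percentage points (default `TRUE`).
#' @return A `pancomp_pgls` object: list with `beta`, `se`, `p_predictor`,
#'   `lambda`, `loglik`, `p_lambda` (LRT of lambda vs 0) and the `gls` fit.
#' @export
fit_pgls <- function(species_table, tree, response = "gc",
                     predictor = "phylum", lambda = NULL,
                     gc_percent = TRUE) {
  df <- as.data.frame(species_table)
  stopifnot(all(c("species", response, predictor) %in% names(df)))
  if (!inherits(tree, "phylo")) stop("tree must be an ape::phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (sum(tree$edge.length) <= 0) stop("degenerate tree: zero total depth")
  if (!setequal(tree$tip.label, df$species) ||
      length(tree$tip.label) != nrow(df)) {
    stop("tree leaves and species rows do not match one to one")
  }
  df <- df[match(tree$tip.label, df$species), , drop = FALSE]
  rownames(df) <- df$species
  if (gc_percent && response == "gc" && max(df$gc, na.rm = TRUE) <= 1) {
    df$gc <- 100 * df$gc
  }
  df[[predictor]] <- factor(df[[predictor]])
  form <- stats::as.formula(paste(response, "~", predictor))
  fit_at <- function(lam) {
    nlme::gls(form, data = df, method = "ML",
              correlation = ape::corPagel(lam, phy = tree, form = ~species,
                                          fixed = TRUE))
  }
  ll_at <- function(lam) as.numeric(stats::logLik(fit_at(lam)))
  if (is.null(lambda)) {
    opt <- stats::optimize(ll_at, c(0, 1), maximum = TRUE, tol = 1e-4)
    # the optimum can sit on a boundary that optimize() never samples
    cand <- c(0, opt$maximum, 1)
    lls <- vapply(cand, ll_at, numeric(1))
    lambda_hat <- cand[which.max(lls)]
  } else {
    stopifnot(lambda >= 0, lambda <= 1)
    lambda_hat <- lambda
  }
  fit <- fit_at(lambda_hat)
  ll <- as.numeric(stats::logLik(fit))
  p_lambda <- if (is.null(lambda)) {
    stat <- max(0, 2 * (ll - ll_at(0)))
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else NA_real_
  an <- stats::anova(fit)
  ct <- summary(fit)$tTable
  structure(
    list(beta = ct[, "Value"], se = ct[, "Std.Error"],
         p_predictor = an[predictor, "p-value"],
         f_predictor = an[predictor, "F-value"],
         lambda = lambda_hat, loglik = ll, p_lambda = p_lambda,
         fit = fit, response = response, predictor = predictor),
    class = "pancomp_pgls"
  )
}

#' @method print pancomp_pgls
#' @export
print.pancomp_pgls <- function(x, ...) {
  cat("Phylogenetic GLS:", x$response, "~", x$predictor, "\n")
  cat("Pagel's lambda =", round(x$lambda, 4),
      "(LRT vs 0: p =", format.pval(x$p_lambda), ")\n")
  cat("ANOVA", x$predictor, "p =", format.pval(x$p_predictor), "\n")
  invisible(x)
}

#' Wilcoxon rank-sum comparison of core-genome fractions
#'
#' Two-sided rank-sum test between two groups of per-strain core-genome
#' fractions (exact when sample sizes allow and there are no ties).
#'
#' @param fractions_a,fractions_b Numeric vectors of core fractions.
#' @return List with `p_value`, `median_a`, `median_b`, `statistic` and a
#'   `all_tied` flag (when every value is identical the test is undefined
#'   and p is reported as 1).
#' @export
wilcoxon_core_fraction <- function(fractions_a, fractions_b) {
  stopifnot(length(fractions_a) >= 1L, length(fractions_b) >= 1L)
  if (length(unique(c(fractions_a, fractions_b))) == 1L) {
    return(list(p_value = 1, median_a = stats::median(fractions_a),
                median_b = stats::median(fractions_b),
                statistic = NA_real_, all_tied = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(fractions_a, fractions_b,
                                            alternative = "two.sided"))
  list(p_value = wt$p.value, median_a = stats::median(fractions_a),
       median_b = stats::median(fractions_b),
       statistic = unname(wt$statistic), all_tied = FALSE)
}
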