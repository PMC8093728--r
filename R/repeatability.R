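#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)` with `k` the number of estimated
#' parameters (including variance components) and `n` the number of
#' observations.
#'
#' @param fit a fitted model with [logLik()] and [stats::nobs()] methods.
#' @return numeric scalar.
#' @export
aicc <- function(fit) {
  ll <- logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Collinearity screen for candidate covariates
#'
#' Pairs of covariates with |Pearson r| above `threshold` cannot enter the
#' same model; from each offending pair one member is removed. Removal
#' follows a documented priority (by default body mass and standard length
#' go first, the redundant whole-body size measures); outside the priority
#' list the member with the larger mean absolute correlation to everything
#' else is dropped.
#'
#' @param covariates data.frame of numeric candidate covariates.
#' @param threshold absolute correlation limit (default 0.7).
#' @param drop_priority character vector of column names to drop first when
#'   implicated.
#' @return character vector of retained column names.
#' @export
screen_collinearity <- function(covariates,
                                threshold = 0.7,
                                drop_priority = c("mass_kg",
                                                  "standard_length_cm")) {
  stopifnot(ncol(covariates) >= 2)
  if (any(vapply(covariates, sd, 1) == 0)) stop("constant covariate supplied")
  keep <- names(covariates)
  repeat {
    cm <- cor(covariates[keep])
    diag(cm) <- 0
    if (max(abs(cm)) <= threshold) break
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    pri <- intersect(drop_priority, pair)
    drop <- if (length(pri)) pri[1] else {
      pair[which.max(colMeans(abs(cm))[pair])]
    }
    keep <- setdiff(keep, drop)
    if (length(keep) < 2) break
  }
  keep
}

# Build a mixed-model formula string: response ~ covariates + (1 | id).
mm_formula <- function(response, covariates, id) {
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  as.formula(paste(response, "~", rhs, paste0("+ (1 | ", id, ")")))
}

fit_mm <- function(form, data, family = "gaussian", reml = FALSE,
                   weights = NULL) {
  if (family == "gaussian") {
    lme4::lmer(form, data = data, REML = reml)
  } else {
    lme4::glmer(form, data = data, family = stats::binomial())
  }
}

#' All-subsets AICc selection of the fixed-effect structure
#'
#' Fits every subset of the (pre-screened) covariates as fixed effects of a
#' mixed model with an individual random intercept, under maximum
#' likelihood, and ranks by AICc. Among the models within `delta` AICc of
#' the best, the most parsimonious (fewest fixed effects, AICc as
#' tie-break) is selected and refitted with REML for reporting (Gaussian
#' case). Subsets that fail to converge are excluded with a warning.
#'
#' @param data data.frame of trips.
#' @param response response column name (already transformed as needed).
#' @param covariates character vector of candidate fixed effects.
#' @param id grouping column name (the individual).
#' @param family `"gaussian"` (lmer) or `"binomial"` (glmer; the response
#'   must then be a two-column success/failure matrix column, see
#'   [repeatability_proportion()]).
#' @param delta AICc threshold for the candidate set (default 4).
#' @return list: `covariates` (selected), `formula`, `fit` (REML refit for
#'   Gaussian, ML otherwise), `table` (all subsets with AICc, delta, k).
#' @export
select_fixed_effects <- function(data, response, covariates,
                                 id = "individual_id",
                                 family = "gaussian", delta = 4) {
  subsets <- list(character(0))
  for (m in seq_along(covariates)) {
    cmb <- combn(covariates, m, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  rows <- list()
  for (s in subsets) {
    form <- mm_formula(response, s, id)
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        fit_mm(form, data, family, reml = FALSE))),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("subset {", paste(s, collapse = ", "), "} failed to converge; excluded")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      covariates = paste(s, collapse = "+"),
      n_fixed = length(s),
      aicc = aicc(fit),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  tab$delta <- tab$aicc - min(tab$aicc)
  tab <- tab[order(tab$aicc), , drop = FALSE]
  cand <- tab[tab$delta < delta, , drop = FALSE]
  best_row <- cand[order(cand$n_fixed, cand$aicc), , drop = FALSE][1, ]
  sel <- if (nzchar(best_row$covariates))
    strsplit(best_row$covariates, "+", fixed = TRUE)[[1]] else character(0)
  form <- mm_formula(response, sel, id)
  fit <- suppressMessages(suppressWarnings(
    fit_mm(form, data, family, reml = (family == "gaussian"))))
  list(covariates = sel, formula = form, fit = fit, table = tab)
}

# Variance components of a (g)lmer fit: named c(id = ..., olre = ...,
# residual = ...). Missing terms are 0/NA.
var_components <- function(fit, id, olre = NULL) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_id <- vc$vcov[vc$grp == id][1]
  v_res <- if (any(vc$grp == "Residual")) vc$vcov[vc$grp == "Residual"][1] else NA_real_
  v_olre <- if (!is.null(olre) && any(vc$grp == olre))
    vc$vcov[vc$grp == olre][1] else NA_real_
  c(id = max(0, v_id), olre = v_olre, residual = v_res)
}

#' Classify a repeatability estimate into a qualitative band
#'
#' Bands: `[0, 0.25]` low, `(0.25, 0.5]` considerable, `(0.5, 0.75]`
#' moderate, `(0.75, 1]` high (boundary values fall in the lower band).
#'
#' @param r repeatability in \[0, 1\].
#' @return character scalar.
#' @export
classify_band <- function(r) {
  stopifnot(r >= 0, r <= 1)
  if (r <= 0.25) "low" else if (r <= 0.5) "considerable"
  else if (r <= 0.75) "moderate" else "high"
}

#' Gaussian repeatability with permutation test and parametric bootstrap
#'
#' Fits `response ~ covariates + (1 | id)` by REML and estimates the
#' population-level repeatability `R = sigma_a^2 / (sigma_a^2 + sigma_e^2)`
#' — the between-individual share of the behaviour's variance. When
#' covariates are included the estimate is an adjusted repeatability
#' (variance explained by the fixed effects is removed first). Significance
#' comes from a permutation test (individual labels permuted across trips;
#' p = fraction of permuted R at or above the observed, with the +1
#' correction), uncertainty from a parametric bootstrap (responses
#' simulated from the fitted model, percentile 95% interval). The
#' individual-level repeatability is the complement `R' = 1 - R`.
#'
#' @param data trips data.frame.
#' @param response,covariates,id column names as in
#'   [select_fixed_effects()].
#' @param n_perm,n_boot permutation / bootstrap replicates (set to 0 to
#'   skip).
#' @param seed optional RNG seed for the resampling.
#' @return object of class `repeatability`: list with `behavior`,
#'   `sigma_alpha2`, `sigma_eps2`, `r`, `r_individual`, `adjusted`,
#'   `ci_low`, `ci_high`, `p_perm`, `band`, `fit`.
#' @export
repeatability_gaussian <- function(data, response, covariates = character(0),
                                   id = "individual_id",
                                   n_perm = 1000, n_boot = 1000,
                                   seed = NULL) {
  if (length(unique(data[[id]])) < 2) stop("need at least 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  form <- mm_formula(response, covariates, id)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = data, REML = TRUE)))
  vc <- var_components(fit, id)
  r_of <- function(v) if (v[["id"]] + v[["residual"]] == 0) 0 else
    v[["id"]] / (v[["id"]] + v[["residual"]])
  r_obs <- r_of(vc)

  p_perm <- NA_real_
  if (n_perm > 0) {
    # permutation statistic: one-way ANOVA F for the individual grouping,
    # computed on the covariate-adjusted response. F is a monotone
    # transform of the *unconstrained* between/within variance ratio, so it
    # is continuous under permutation; the REML-based R itself sits on the
    # sigma_alpha^2 = 0 boundary with positive probability, which would
    # leave an atom at p = 1 and a conservative, non-uniform null p
    y <- data[[response]]
    if (length(covariates)) {
      y <- stats::resid(lm(stats::reformulate(covariates, response), data))
    }
    g <- as.factor(data[[id]])
    f_of <- function(y, g) {
      m <- tapply(y, g, mean)
      n_i <- tabulate(g)
      msb <- sum(n_i * (m[levels(g)] - mean(y))^2) / (nlevels(g) - 1)
      msw <- sum((y - m[g])^2) / (length(y) - nlevels(g))
      msb / msw
    }
    f_obs <- f_of(y, g)
    f_perm <- vapply(seq_len(n_perm),
                     function(b) f_of(y, sample(g)), numeric(1))
    p_perm <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  }

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ys <- stats::simulate(fit, nsim = n_boot, use.u = FALSE)
    r_boot <- vapply(ys, function(y) {
      f2 <- suppressMessages(suppressWarnings(lme4::refit(fit, y)))
      r_of(var_components(f2, id))
    }, numeric(1))
    ci <- unname(quantile(r_boot, c(0.025, 0.975)))
  }

  structure(list(
    behavior = response,
    sigma_alpha2 = unname(vc[["id"]]),
    sigma_eps2 = unname(vc[["residual"]]),
    r = r_obs, r_individual = 1 - r_obs,
    adjusted = length(covariates) > 0,
    ci_low = ci[1], ci_high = ci[2],
    p_perm = p_perm,
    band = classify_band(min(1, max(0, r_obs))),
    fit = fit
  ), class = "repeatability")
}

#' Link-scale repeatability for proportion behaviours
#'
#' For per-trip proportions with binomial denominators (e.g. benthic dives
#' out of all dives of the trip), fits a binomial logit-link GLMM with an
#' individual random intercept and an observation-level random effect
#' (OLRE) absorbing overdispersion, and reports the link-scale
#' repeatability `R = sigma_a^2 / (sigma_a^2 + sigma_olre^2 + pi^2/3)`,
#' where `pi^2/3` is the logit distribution-specific variance. No
#' confidence interval or permutation test is produced for proportion
#' responses.
#'
#' @param data trips data.frame.
#' @param successes,trials column names of the binomial numerator and
#'   denominator counts.
#' @param covariates,id as in [repeatability_gaussian()].
#' @return object of class `repeatability` (with `ci_*` and `p_perm` NA and
#'   `distribution_variance = pi^2/3`).
#' @export
repeatability_proportion <- function(data, successes, trials,
                                     covariates = character(0),
                                     id = "individual_id") {
  if (length(unique(data[[id]])) < 2) stop("need at least 2 individuals")
  k <- data[[successes]]
  n <- data[[trials]]
  if (all(k == 0) || all(k == n)) stop("all proportions are 0 or 1")
  d <- data
  d$.obs <- factor(seq_len(nrow(d)))
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  form <- as.formula(paste0("cbind(", successes, ", ", trials, " - ",
                            successes, ") ~ ", rhs,
                            " + (1 | ", id, ") + (1 | .obs)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = d, family = stats::binomial())))
  vc <- var_components(fit, id, olre = ".obs")
  dv <- pi^2 / 3
  denom <- vc[["id"]] + vc[["olre"]] + dv
  r_obs <- unname(vc[["id"]] / denom)
  structure(list(
    behavior = successes,
    sigma_alpha2 = unname(vc[["id"]]),
    sigma_eps2 = unname(vc[["olre"]] + dv),
    sigma_olre2 = unname(vc[["olre"]]),
    distribution_variance = dv,
    r = r_obs, r_individual = 1 - r_obs,
    adjusted = length(covariates) > 0,
    ci_low = NA_real_, ci_high = NA_real_, p_perm = NA_real_,
    band = classify_band(min(1, max(0, r_obs))),
    fit = fit
  ), class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability of %s%s\n", x$behavior,
              if (x$adjusted) " (adjusted)" else ""))
  cat(sprintf("  sigma_alpha2 = %.4f, sigma_eps2 = %.4f\n",
              x$sigma_alpha2, x$sigma_eps2))
  cat(sprintf("  R = %.3f (%s), R' = 1 - R = %.3f\n", x$r, x$band,
              x$r_individual))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  bootstrap 95%% CI [%.3f, %.3f]\n", x$ci_low, x$ci_high))
  }
  if (!is.na(x$p_perm)) cat(sprintf("  permutation p = %.4f\n", x$p_perm))
  invisible(x)
}
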