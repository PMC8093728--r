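#' Circular standard deviation of angles
#'
#' `sqrt(-2 ln Rbar) * 180/pi`, with `Rbar` the mean resultant length of
#' the angles. 0 when all angles coincide; rotation-invariant.
#'
#' @param deg angles in degrees.
#' @return circular SD in degrees.
#' @export
circ_sd <- function(deg) {
  rad <- deg * pi / 180
  rbar <- sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
  rbar <- min(1, rbar)
  sqrt(-2 * log(rbar)) * 180 / pi
}

#' Coefficient of variation
#' @param x numeric vector.
#' @return `sd(x)/mean(x)`, or NA when the mean is 0 (CV undefined).
#' @export
cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sd(x) / m
}

#' Per-individual consistency profile
#'
#' Summarizes how consistent one individual is across its trips: the
#' coefficient of variation (SD/mean; smaller = more consistent) of each
#' foraging behaviour, the circular SD of trip bearings (CV is meaningless
#' for angles), the individual's Foraging Site Fidelity Index, and the mean
#' and CV of the trip success/efficiency indices.
#'
#' @param trips data.frame of one individual's trips with columns
#'   `duration_h`, `max_range`, `modal_depth`, `dive_rate`, `prop_benthic`,
#'   `prop_daylight`, `total_distance`, `horizontal_distance`,
#'   `bearing_distal`, and optionally `ftsi`, `ftei` (>= 3 rows).
#' @param fsfi the individual's FSFI (from [fsfi()]), or NA.
#' @param individual_id id string recorded in the output.
#' @return one-row data.frame of class `consistency_profile`.
#' @export
consistency_profile <- function(trips, fsfi = NA_real_,
                                individual_id = trips$individual_id[1]) {
  if (nrow(trips) < 3) stop("consistency requires at least 3 trips")
  beh <- c("duration_h", "max_range", "modal_depth", "dive_rate",
           "prop_benthic", "prop_daylight", "total_distance",
           "horizontal_distance")
  out <- data.frame(individual_id = individual_id, stringsAsFactors = FALSE)
  for (b in beh) out[[paste0("cv_", b)]] <- cv(trips[[b]])
  out$bearing_circ_sd <- circ_sd(trips$bearing_distal)
  out$fsfi <- fsfi
  out$mean_ftsi <- if (is.null(trips$ftsi)) NA_real_ else mean(trips$ftsi)
  out$mean_ftei <- if (is.null(trips$ftei)) NA_real_ else mean(trips$ftei)
  out$cv_ftsi <- if (is.null(trips$ftsi)) NA_real_ else cv(trips$ftsi)
  out$cv_ftei <- if (is.null(trips$ftei)) NA_real_ else cv(trips$ftei)
  class(out) <- c("consistency_profile", "data.frame")
  out
}

# All-subsets AICc selection for an ordinary linear model; parsimony rule
# as in select_fixed_effects().
select_lm <- function(data, response, predictors, delta = 4) {
  subsets <- list(character(0))
  for (m in seq_along(predictors)) {
    subsets <- c(subsets, combn(sort(predictors), m, simplify = FALSE))
  }
  rows <- lapply(subsets, function(s) {
    rhs <- if (length(s)) paste(s, collapse = " + ") else "1"
    fit <- lm(as.formula(paste(response, "~", rhs)), data = data)
    data.frame(covariates = paste(s, collapse = "+"), n_fixed = length(s),
               aicc = aicc(fit), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$delta <- tab$aicc - min(tab$aicc)
  tab <- tab[order(tab$aicc), , drop = FALSE]
  cand <- tab[tab$delta < delta, , drop = FALSE]
  best <- cand[order(cand$n_fixed, cand$aicc), , drop = FALSE][1, ]
  sel <- if (nzchar(best$covariates))
    strsplit(best$covariates, "+", fixed = TRUE)[[1]] else character(0)
  rhs <- if (length(sel)) paste(sel, collapse = " + ") else "1"
  fit <- lm(as.formula(paste(response, "~", rhs)), data = data)
  list(covariates = sel, fit = fit, table = tab)
}

#' Linear models linking individual consistency to foraging success
#'
#' Fits the four consistency-to-payoff models: mean FTSI, mean FTEI, and
#' their CVs, each regressed on the per-individual consistency measures
#' (CVs of trip duration, maximum range, modal depth, dive rate, proportion
#' benthic and proportion daylight, the circular SD of bearing, and the
#' FSFI). The CVs of total and horizontal distance are excluded a priori
#' (collinear with trip duration). Each response gets an all-subsets AICc
#' selection; the report carries AIC, the likelihood-ratio test of the
#' selected model against the intercept-only null, r^2, and per-covariate
#' estimates with SE, t and 95% CI.
#'
#' @param profiles data.frame of [consistency_profile()] rows (>= 10
#'   complete individuals).
#' @param responses response columns (default the four indices).
#' @param predictors predictor columns; defaults as described.
#' @param delta AICc selection threshold.
#' @return named list of model reports; each has `response`, `formula`,
#'   `covariates`, `aic`, `loglik`, `l_ratio`, `p`, `r2`, `coefficients`
#'   (data.frame est/se/t/ci), `fit`, `table`.
#' @export
fit_consistency_models <- function(profiles,
                                   responses = c("mean_ftsi", "mean_ftei",
                                                 "cv_ftsi", "cv_ftei"),
                                   predictors = c("cv_duration_h",
                                                  "cv_max_range",
                                                  "cv_modal_depth",
                                                  "cv_dive_rate",
                                                  "cv_prop_benthic",
                                                  "cv_prop_daylight",
                                                  "bearing_circ_sd",
                                                  "fsfi"),
                                   delta = 4) {
  predictors <- intersect(predictors, names(profiles))
  d <- profiles[complete.cases(profiles[c(responses, predictors)]), ,
                drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 individuals with complete profiles")
  qr_ok <- qr(as.matrix(d[predictors]))$rank == length(predictors)
  if (!qr_ok) stop("rank-deficient predictor design")
  reports <- list()
  for (resp in responses) {
    sel <- select_lm(d, resp, predictors, delta = delta)
    fit <- sel$fit
    null_fit <- lm(as.formula(paste(resp, "~ 1")), data = d)
    lr <- 2 * (as.numeric(logLik(fit)) - as.numeric(logLik(null_fit)))
    df_lr <- length(coef(fit)) - 1L
    p <- if (df_lr > 0) pchisq(lr, df_lr, lower.tail = FALSE) else NA_real_
    sm <- summary(fit)
    ci <- confint(fit)
    coefs <- data.frame(
      covariate = rownames(sm$coefficients),
      estimate = sm$coefficients[, 1],
      se = sm$coefficients[, 2],
      t = sm$coefficients[, 3],
      ci_low = ci[, 1], ci_high = ci[, 2],
      row.names = NULL, stringsAsFactors = FALSE
    )
    reports[[resp]] <- list(
      response = resp,
      formula = paste(resp, "~", if (length(sel$covariates))
        paste(sel$covariates, collapse = " + ") else "1"),
      covariates = sel$covariates,
      aic = stats::AIC(fit),
      loglik = as.numeric(logLik(fit)),
      l_ratio = lr, p = p, r2 = sm$r.squared,
      coefficients = coefs,
      fit = fit, table = sel$table
    )
  }
  reports
}
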