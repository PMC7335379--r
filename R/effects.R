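#' Read-out effect-structure parameters
#'
#' The generative model is the inverse of the fitted inference layer:
#' continuous read-outs are linear (or, for pro-collagen, a smoothed step) in
#' patient covariates plus noise, and the intact/released outcome is drawn
#' from a logistic model.  Defaults are calibrated so that the fitted models
#' recover an age slope of 0.96 %/y for relative area, an age log-odds of
#' 0.19 for staying intact, a linear age estimate of about -15 ng/ml/y for
#' pro-collagen (induced by a 5-fold plateau drop around 25 y), and an
#' expected release rate of 10/41 under the default cohort.
#'
#' `release_intercept = NULL` or `procol_low_plateau = NULL` triggers
#' numerical calibration against `cohort` (see
#' [calibrate_release_intercept()] and [calibrate_procollagen_step()]);
#' the documented defaults are the frozen results of that calibration for
#' [cohort_params()] defaults.
#'
#' @param area_intercept,area_age_slope,area_noise_sd relative-area model:
#'   percent, percent per year, percent.
#' @param area_male_effect,area_semitend_effect optional covariate effects on
#'   relative area (percent; default 0).
#' @param procol_high_plateau,procol_low_plateau pro-collagen plateaus, ng/ml
#'   (high plateau is `ratio` times the low one when calibrated).
#' @param procol_threshold_age centre of the plateau transition, years.
#' @param procol_sigmoid_width transition width, years.
#' @param procol_noise_sd additive assay noise, ng/ml (concentrations clamp
#'   at zero).
#' @param release_intercept,release_age_coef,release_male_coef,release_semitend_coef
#'   log-odds model for *staying intact* (intact coded 1).
#' @param release_time_range hours; programmed release times are uniform on
#'   this span.
#' @param asma_lognormal_params,tnmd_lognormal_params `c(meanlog, sdlog)` for
#'   the age-independent housekeeping-normalized blot ratios.
#' @param mmp2_active_fraction_mean,mmp2_active_fraction_sd Gaussian clipped
#'   to the unit interval.
#' @param mmp2_intensity_baseline,mmp2_intensity_age_slope,mmp2_intensity_noise_sd
#'   active-MMP2 band intensity model, A.U.
#' @param tubulin_lognormal_params loading-control band intensity, A.U.
#' @param p_low_tubulin,low_tubulin_factor occasional degraded lysates with
#'   reduced loading-control signal (these are what the outlier rule flags).
#' @param cohort a [cohort_params()] used only when calibration is requested.
#' @return a list of class `effect_params`.
#' @export
effect_params <- function(area_intercept = 28, area_age_slope = 0.96,
                          area_noise_sd = 20,
                          area_male_effect = 0, area_semitend_effect = 0,
                          procol_high_plateau = NULL,
                          procol_low_plateau = NULL,
                          procol_threshold_age = 25,
                          procol_sigmoid_width = 2,
                          procol_noise_sd = 100,
                          release_intercept = NULL,
                          release_age_coef = 0.19,
                          release_male_coef = 1.6,
                          release_semitend_coef = -2.7,
                          release_time_range = c(2, 37),
                          asma_lognormal_params = c(meanlog = 0, sdlog = 0.8),
                          tnmd_lognormal_params = c(meanlog = -3.5, sdlog = 0.6),
                          mmp2_active_fraction_mean = 0.35,
                          mmp2_active_fraction_sd = 0.05,
                          mmp2_intensity_baseline = 30,
                          mmp2_intensity_age_slope = -0.17,
                          mmp2_intensity_noise_sd = 9.7,
                          tubulin_lognormal_params = c(meanlog = log(100), sdlog = 0.2),
                          p_low_tubulin = 0.1,
                          low_tubulin_factor = 0.35,
                          cohort = cohort_params()) {
  if (is.null(procol_low_plateau) || is.null(procol_high_plateau)) {
    plat <- calibrate_procollagen_step(cohort = cohort,
                                       threshold_age = procol_threshold_age,
                                       width = procol_sigmoid_width,
                                       noise_sd = procol_noise_sd,
                                       release_intercept = release_intercept,
                                       release_age_coef = release_age_coef,
                                       release_male_coef = release_male_coef,
                                       release_semitend_coef = release_semitend_coef)
    procol_low_plateau <- procol_low_plateau %||% plat[["low"]]
    procol_high_plateau <- procol_high_plateau %||% plat[["high"]]
  }
  if (is.null(release_intercept)) {
    release_intercept <- calibrate_release_intercept(
      cohort = cohort, target_release_rate = 10 / 41,
      age_coef = release_age_coef, male_coef = release_male_coef,
      semitend_coef = release_semitend_coef)
  }
  stop_if(procol_high_plateau <= procol_low_plateau,
          "procol_high_plateau must exceed procol_low_plateau")
  stop_if(mmp2_active_fraction_mean - 3 * mmp2_active_fraction_sd < 0 ||
            mmp2_active_fraction_mean + 3 * mmp2_active_fraction_sd > 1,
          "mmp2 active fraction mean +/- 3 sd must stay within [0, 1]")
  stop_if(any(c(area_noise_sd, procol_noise_sd, mmp2_intensity_noise_sd) < 0),
          "noise sds must be non-negative")
  structure(list(
    area_intercept = area_intercept, area_age_slope = area_age_slope,
    area_noise_sd = area_noise_sd, area_male_effect = area_male_effect,
    area_semitend_effect = area_semitend_effect,
    procol_high_plateau = procol_high_plateau,
    procol_low_plateau = procol_low_plateau,
    procol_threshold_age = procol_threshold_age,
    procol_sigmoid_width = procol_sigmoid_width,
    procol_noise_sd = procol_noise_sd,
    release_intercept = release_intercept,
    release_age_coef = release_age_coef,
    release_male_coef = release_male_coef,
    release_semitend_coef = release_semitend_coef,
    release_time_range = release_time_range,
    asma_lognormal_params = asma_lognormal_params,
    tnmd_lognormal_params = tnmd_lognormal_params,
    mmp2_active_fraction_mean = mmp2_active_fraction_mean,
    mmp2_active_fraction_sd = mmp2_active_fraction_sd,
    mmp2_intensity_baseline = mmp2_intensity_baseline,
    mmp2_intensity_age_slope = mmp2_intensity_age_slope,
    mmp2_intensity_noise_sd = mmp2_intensity_noise_sd,
    tubulin_lognormal_params = tubulin_lognormal_params,
    p_low_tubulin = p_low_tubulin,
    low_tubulin_factor = low_tubulin_factor), class = "effect_params")
}

## P(intact | age, male, semitend) under the generative logistic model
intact_prob <- function(age, male, semitend, intercept, age_coef, male_coef,
                        semitend_coef) {
  plogis(intercept + age_coef * age + male_coef * male + semitend_coef * semitend)
}

## tendon-level covariate class probabilities implied by cohort params
tendon_class_probs <- function(cohort) {
  p2 <- cohort$p_second_tendon
  p_st <- (cohort$p_semitendinosus + p2 * (1 - cohort$p_semitendinosus)) / (1 + p2)
  pm <- cohort$p_male
  expand <- expand.grid(male = c(0, 1), semitend = c(0, 1))
  expand$p <- ifelse(expand$male == 1, pm, 1 - pm) *
    ifelse(expand$semitend == 1, p_st, 1 - p_st)
  expand
}

#' Solve the intact-model intercept for a target release rate
#'
#' The log-odds intercept of the intact/released model is not identified by
#' the published covariate estimates; it is solved numerically so that the
#' expected release fraction over the cohort's age/gender/tendon distribution
#' equals `target_release_rate` (default 10/41).
#'
#' @param cohort a [cohort_params()].
#' @param target_release_rate expected fraction of released tendons.
#' @param age_coef,male_coef,semitend_coef intact-model log-odds coefficients.
#' @return the intercept (log-odds of intact at age 0, female, gracilis).
#' @export
calibrate_release_intercept <- function(cohort = cohort_params(),
                                        target_release_rate = 10 / 41,
                                        age_coef = 0.19, male_coef = 1.6,
                                        semitend_coef = -2.7) {
  grid <- seq(cohort$age_range[1], cohort$age_range[2], length.out = 2001)
  w <- cohort_age_density(grid, cohort)
  w <- w / sum(w)
  cls <- tendon_class_probs(cohort)
  release_rate <- function(b0) {
    r <- 0
    for (k in seq_len(nrow(cls))) {
      p_int <- intact_prob(grid, cls$male[k], cls$semitend[k],
                           b0, age_coef, male_coef, semitend_coef)
      r <- r + cls$p[k] * sum(w * (1 - p_int))
    }
    r
  }
  uniroot(function(b0) release_rate(b0) - target_release_rate,
          lower = -30, upper = 10, tol = 1e-10)$root
}

## expected value of max(N(m, s), 0)
clamped_normal_mean <- function(m, s) {
  if (s <= 0) return(pmax(m, 0))
  m * pnorm(m / s) + s * dnorm(m / s)
}

## pro-collagen mean curve before noise
procol_mu <- function(age, low, high, threshold_age, width) {
  low + (high - low) * plogis((threshold_age - age) / width)
}

#' Calibrate the pro-collagen plateau pair
#'
#' With the plateau ratio fixed (default 5-fold) and the transition centred
#' at `threshold_age`, solves the plateau scale so that the *expected linear
#' age slope* of the clamped-at-zero read-out, fitted over intact tendons
#' only (intact-probability-weighted age distribution), equals
#' `target_slope` ng/ml per year.
#'
#' @param cohort a [cohort_params()].
#' @param target_slope expected linear age estimate, ng/ml per year.
#' @param ratio high/low plateau ratio.
#' @param threshold_age,width transition centre and width, years.
#' @param noise_sd additive assay noise (enters through zero-clamping).
#' @param release_intercept,release_age_coef,release_male_coef,release_semitend_coef
#'   intact model used for the weighting; `release_intercept = NULL` solves it
#'   first.
#' @return `c(low = ..., high = ...)` in ng/ml.
#' @export
calibrate_procollagen_step <- function(cohort = cohort_params(),
                                       target_slope = -15, ratio = 5,
                                       threshold_age = 25, width = 2,
                                       noise_sd = 100,
                                       release_intercept = NULL,
                                       release_age_coef = 0.19,
                                       release_male_coef = 1.6,
                                       release_semitend_coef = -2.7) {
  if (is.null(release_intercept)) {
    release_intercept <- calibrate_release_intercept(
      cohort, 10 / 41, release_age_coef, release_male_coef, release_semitend_coef)
  }
  grid <- seq(cohort$age_range[1], cohort$age_range[2], length.out = 2001)
  f <- cohort_age_density(grid, cohort)
  cls <- tendon_class_probs(cohort)
  p_int <- rowSums(vapply(seq_len(nrow(cls)), function(k) {
    cls$p[k] * intact_prob(grid, cls$male[k], cls$semitend[k],
                           release_intercept, release_age_coef,
                           release_male_coef, release_semitend_coef)
  }, numeric(length(grid))))
  w <- f * p_int
  w <- w / sum(w)
  abar <- sum(w * grid)
  denom <- sum(w * (grid - abar)^2)
  slope_for <- function(low) {
    mu <- procol_mu(grid, low, ratio * low, threshold_age, width)
    muc <- clamped_normal_mean(mu, noise_sd)
    sum(w * (grid - abar) * muc) / denom
  }
  low <- uniroot(function(L) slope_for(L) - target_slope,
                 lower = 1, upper = 5000, tol = 1e-8)$root
  c(low = low, high = ratio * low)
}

#' Generate per-tendon read-outs with the study's effect structure
#'
#' Per tendon: relative surface area at 48 h is affine in covariates with
#' Gaussian noise; pro-collagen follows a smoothed 5-fold step around the
#' threshold age, clamped at zero; intact/released is a Bernoulli draw from
#' the logistic model (intact coded 1); blot ratios are age-independent
#' lognormals; active-MMP2 intensity is linear in age; the MMP2 active
#' fraction is Gaussian clipped to the unit interval.  Released tendons carry
#' `NA` for every post-release biochemical read-out, mirroring the exclusion
#' of released micro-tissues from further processing, and carry a programmed
#' release time drawn uniformly from `release_time_range`.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param effects an [effect_params()].
#' @param seed integer seed.
#' @return the cohort data.frame extended with read-out columns
#'   (`intact`, `release_time_h`, `relative_area_pct`, `pro_collagen_ng_ml`,
#'   `tnmd_tubulin`, `asma_tubulin`, `active_mmp2_au`, `mmp2_active_fraction`,
#'   `tubulin_au`).
#' @export
generate_readouts <- function(cohort, effects = effect_params(), seed = 1L) {
  stop_if(!is.data.frame(cohort) || nrow(cohort) == 0L, "cohort must be a non-empty data.frame")
  stop_if(!inherits(effects, "effect_params"), "effects must come from effect_params()")
  e <- effects
  with_seed(seed, {
    n <- nrow(cohort)
    age <- cohort$age_y
    male <- as.numeric(cohort$gender == "M")
    st <- as.numeric(cohort$tendon == "ST")

    p_int <- intact_prob(age, male, st, e$release_intercept,
                         e$release_age_coef, e$release_male_coef,
                         e$release_semitend_coef)
    intact <- rbinom(n, 1, p_int)
    release_time <- ifelse(intact == 1, NA_real_,
                           runif(n, e$release_time_range[1], e$release_time_range[2]))

    rel_area <- e$area_intercept + e$area_age_slope * age +
      e$area_male_effect * male + e$area_semitend_effect * st +
      rnorm(n, 0, e$area_noise_sd)

    procol <- pmax(procol_mu(age, e$procol_low_plateau, e$procol_high_plateau,
                             e$procol_threshold_age, e$procol_sigmoid_width) +
                     rnorm(n, 0, e$procol_noise_sd), 0)
    tnmd <- rlnorm(n, e$tnmd_lognormal_params[["meanlog"]],
                   e$tnmd_lognormal_params[["sdlog"]])
    asma <- rlnorm(n, e$asma_lognormal_params[["meanlog"]],
                   e$asma_lognormal_params[["sdlog"]])
    mmp2 <- pmax(e$mmp2_intensity_baseline + e$mmp2_intensity_age_slope * age +
                   rnorm(n, 0, e$mmp2_intensity_noise_sd), 0)
    frac <- clamp(rnorm(n, e$mmp2_active_fraction_mean, e$mmp2_active_fraction_sd), 0, 1)
    tubulin <- rlnorm(n, e$tubulin_lognormal_params[["meanlog"]],
                      e$tubulin_lognormal_params[["sdlog"]])
    tubulin <- tubulin * ifelse(runif(n) < e$p_low_tubulin, e$low_tubulin_factor, 1)

    released <- intact == 0
    procol[released] <- NA_real_
    tnmd[released] <- NA_real_
    asma[released] <- NA_real_
    mmp2[released] <- NA_real_
    frac[released] <- NA_real_
    tubulin[released] <- NA_real_

    out <- cohort
    out$intact <- intact
    out$release_time_h <- release_time
    out$relative_area_pct <- rel_area
    out$pro_collagen_ng_ml <- procol
    out$tnmd_tubulin <- tnmd
    out$asma_tubulin <- asma
    out$active_mmp2_au <- mmp2
    out$mmp2_active_fraction <- frac
    out$tubulin_au <- tubulin
    out
  })
}
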