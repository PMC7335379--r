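#' Cohort generator parameters
#'
#' Defaults emulate a 36-patient / 41-tendon hamstring-autograft cohort:
#' patient age averaging 27.9 y (sd 12.9 y) within 12-55 y, 20/36 male,
#' 30/41 semitendinosus tendons, and 5/36 patients contributing both a
#' semitendinosus and a gracilis tendon.
#'
#' `mean_age` and `sd_age` are the *target moments of the truncated
#' distribution*: the parent normal's parameters are solved internally by
#' moment matching so that ages clipped to `age_range` reproduce the targets
#' as closely as a truncated normal allows.
#'
#' @param n_patients number of patients.
#' @param age_range numeric length 2, min and max age in years.
#' @param mean_age,sd_age target mean and sd of the (truncated) age
#'   distribution, years.
#' @param p_male probability a patient is male.
#' @param p_semitendinosus probability a patient's first tendon is
#'   semitendinosus (default 25/31, which yields 30/41 semitendinosus tendons
#'   in expectation when second tendons are always the other type).
#' @param p_second_tendon probability a patient contributes both tendon types
#'   (default 5/36).
#' @param seed integer seed.
#' @return a list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 36L,
                          age_range = c(12, 55),
                          mean_age = 27.9, sd_age = 12.9,
                          p_male = 20 / 36,
                          p_semitendinosus = 25 / 31,
                          p_second_tendon = 5 / 36,
                          seed = 1L) {
  stop_if(!is_count(n_patients) || n_patients < 1, "n_patients must be a positive count")
  stop_if(length(age_range) != 2L || age_range[1] >= age_range[2],
          "age_range must be (min, max) with min < max")
  stop_if(!is_prob(p_male) || !is_prob(p_semitendinosus) || !is_prob(p_second_tendon),
          "probabilities must lie in [0, 1]")
  stop_if(sd_age <= 0, "sd_age must be positive")
  parent <- truncnorm_match(mean_age, sd_age, age_range[1], age_range[2])
  structure(list(n_patients = as.integer(n_patients), age_range = age_range,
                 mean_age = mean_age, sd_age = sd_age, p_male = p_male,
                 p_semitendinosus = p_semitendinosus,
                 p_second_tendon = p_second_tendon,
                 parent_mu = parent[1], parent_sigma = parent[2],
                 seed = as.integer(seed)),
            class = "cohort_params")
}

## moments of a normal(mu, s) truncated to [a, b]
truncnorm_moments <- function(mu, s, a, b) {
  al <- (a - mu) / s; be <- (b - mu) / s
  Z <- pnorm(be) - pnorm(al)
  m <- mu + s * (dnorm(al) - dnorm(be)) / Z
  v <- s^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z -
                ((dnorm(al) - dnorm(be)) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

## solve parent (mu, sigma) so that truncated moments best match the targets
truncnorm_match <- function(target_mean, target_sd, a, b) {
  obj <- function(p) {
    ms <- truncnorm_moments(p[1], exp(p[2]), a, b)
    sum((ms - c(target_mean, target_sd))^2)
  }
  o <- optim(c(target_mean, log(target_sd)), obj,
             control = list(maxit = 2000, reltol = 1e-12))
  c(mu = o$par[1], sigma = exp(o$par[2]))
}

## tail-stable inverse-CDF sampler for the truncated normal
rtruncnorm <- function(n, mu, s, a, b) {
  ## work in the upper tail when the window sits far above mu (and vice versa)
  if ((a - mu) / s > 0) {
    pa <- pnorm(a, mu, s, lower.tail = FALSE)
    pb <- pnorm(b, mu, s, lower.tail = FALSE)
    u <- runif(n)
    qnorm(pa + u * (pb - pa), mu, s, lower.tail = FALSE)
  } else if ((b - mu) / s < 0) {
    pa <- pnorm(a, mu, s)
    pb <- pnorm(b, mu, s)
    qnorm(pa + runif(n) * (pb - pa), mu, s)
  } else {
    pa <- pnorm(a, mu, s)
    pb <- pnorm(b, mu, s)
    qnorm(pa + runif(n) * (pb - pa), mu, s)
  }
}

## density of the cohort age distribution (for calibration integrals)
cohort_age_density <- function(age, params) {
  a <- params$age_range[1]; b <- params$age_range[2]
  mu <- params$parent_mu; s <- params$parent_sigma
  Z <- pnorm(b, mu, s) - pnorm(a, mu, s)
  ifelse(age >= a & age <= b, dnorm(age, mu, s) / Z, 0)
}

#' Generate a synthetic patient cohort
#'
#' Draws one record per tendon.  Ages come from the moment-matched truncated
#' normal clipped to `age_range`; gender and first-tendon type are Bernoulli
#' draws; a patient contributing a second tendon contributes the *other*
#' tendon type with the same age and gender.
#'
#' @param params a [cohort_params()].
#' @return data.frame with columns `patient_id`, `tendon_id`, `age_y`,
#'   `gender` (`"M"`/`"F"`), `tendon` (`"ST"`/`"G"`).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stop_if(!inherits(params, "cohort_params"), "params must come from cohort_params()")
  with_seed(params$seed, {
    n <- params$n_patients
    age <- rtruncnorm(n, params$parent_mu, params$parent_sigma,
                      params$age_range[1], params$age_range[2])
    age <- round(age, 1)
    male <- rbinom(n, 1, params$p_male) == 1L
    first_st <- rbinom(n, 1, params$p_semitendinosus) == 1L
    second <- rbinom(n, 1, params$p_second_tendon) == 1L
    rows <- lapply(seq_len(n), function(i) {
      tendons <- if (second[i]) c(first_st[i], !first_st[i]) else first_st[i]
      data.frame(patient_id = i,
                 tendon_id = NA_integer_,
                 age_y = age[i],
                 gender = if (male[i]) "M" else "F",
                 tendon = ifelse(tendons, "ST", "G"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$tendon_id <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
  })
}
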