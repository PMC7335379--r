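fake_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age_y = round(runif(n, 12, 55), 1),
             gender = sample(c("M", "F"), n, replace = TRUE),
             tendon = sample(c("ST", "G"), n, replace = TRUE))
}

test_that("a noiseless affine read-out is fitted exactly", {
  d <- fake_table(20, 2)
  d$y <- 3 + 2 * d$age_y
  fit <- fit_linear(model_input(d, "y"))
  cf <- fit$coefficients
  g <- function(t) cf$estimate[cf$term == t]
  expect_equal(g("age"), 2, tolerance = 1e-12)
  expect_equal(g("male"), 0, tolerance = 1e-10)
  expect_equal(g("semitend"), 0, tolerance = 1e-10)
  expect_equal(fit$fit_stat, 1, tolerance = 1e-12)
})

test_that("OLS matches the normal-equations oracle on a random 12-row table", {
  d <- fake_table(12, 5)
  set.seed(6)
  d$y <- 10 + 0.5 * d$age_y + rnorm(12, 0, 4)
  fit <- fit_linear(model_input(d, "y"))
  X <- cbind(1, d$age_y, as.numeric(d$gender == "M"), as.numeric(d$tendon == "ST"))
  o <- oracle_ols(d$y, X)
  cf <- fit$coefficients
  expect_equal(cf$estimate, o$estimate, tolerance = 1e-10)
  expect_equal(cf$std_error, o$se, tolerance = 1e-10)
  expect_equal(cf$p_value, o$p, tolerance = 1e-10)
  expect_equal(fit$fit_stat, o$r2, tolerance = 1e-10)
})

test_that("rank-deficient designs are refused with the collinear column named", {
  d <- fake_table(15, 7)
  d$tendon <- "ST"  # constant -> collinear with intercept
  d$y <- rnorm(15)
  expect_error(fit_linear(model_input(d, "y")), "semitend")
})

test_that("flipping the gender coding flips only that coefficient's sign", {
  d <- fake_table(40, 8)
  set.seed(9)
  d$y <- 5 + 0.3 * d$age_y + 2 * (d$gender == "M") + rnorm(40)
  f1 <- fit_linear(model_input(d, "y"))
  d2 <- d
  d2$gender <- ifelse(d$gender == "M", "F", "M")  # male = 0 coding
  f2 <- fit_linear(model_input(d2, "y"))
  g <- function(f, t, col = "estimate") {
    cf <- f$coefficients; cf[cf$term == t, col]
  }
  expect_equal(g(f2, "male"), -g(f1, "male"), tolerance = 1e-10)
  expect_equal(g(f2, "age"), g(f1, "age"), tolerance = 1e-10)
  expect_equal(g(f2, "semitend"), g(f1, "semitend"), tolerance = 1e-10)
  expect_equal(f2$fit_stat, f1$fit_stat, tolerance = 1e-10)
})

test_that("logistic MLE matches a grid-search oracle on a hand-built 8-row table", {
  ## single binary covariate: fit intercept + slope only
  d <- data.frame(y = c(0, 0, 1, 0, 1, 1, 1, 0),
                  x = c(0, 0, 0, 0, 1, 1, 1, 1))
  fit <- glm(y ~ x, family = binomial(), data = d,
             control = list(epsilon = 1e-10, maxit = 100))
  o <- oracle_logit_grid(d$y, d$x)
  expect_equal(unname(coef(fit)[1]), o[1], tolerance = 5e-4)
  expect_equal(unname(coef(fit)[2]), o[2], tolerance = 5e-4)
})

test_that("fit_logistic recovers a generating age effect and reports McFadden pseudo-R2", {
  co <- generate_cohort(cohort_params(n_patients = 440, seed = 10))
  ro <- generate_readouts(co, effect_params(), seed = 11)
  fit <- fit_logistic(model_input(ro, "intact", binary = TRUE))
  cf <- fit$coefficients
  expect_lt(abs(cf$estimate[cf$term == "age"] - 0.19), 0.1)
  ## pseudo-R2 recomputed directly from the two log-likelihoods
  y <- ro$intact
  m1 <- glm(intact ~ age_y + I(gender == "M") + I(tendon == "ST"),
            family = binomial(), data = ro)
  m0 <- glm(intact ~ 1, family = binomial(), data = ro)
  expect_equal(fit$fit_stat, 1 - as.numeric(logLik(m1)) / as.numeric(logLik(m0)),
               tolerance = 1e-6)
  expect_identical(fit$fit_stat_name, "pseudo-R2")
})

test_that("a null outcome yields pseudo-R2 near zero and ~5% rejections", {
  rej <- 0; pr2 <- c()
  for (s in 1:40) {
    d <- fake_table(500, s + 100)
    set.seed(s)
    d$y <- rbinom(500, 1, 0.7)  # independent of covariates
    fit <- fit_logistic(model_input(d, "y", binary = TRUE))
    cf <- fit$coefficients
    rej <- rej + (cf$p_value[cf$term == "age"] < 0.05)
    pr2 <- c(pr2, fit$fit_stat)
  }
  expect_lt(mean(pr2), 0.02)
  expect_lte(rej, 7)  # ~5% of 40, generous binomial slack
})

test_that("single-class outcomes and perfect separation are refused", {
  d <- fake_table(20, 12)
  d$y <- 1
  expect_error(fit_logistic(model_input(d, "y", binary = TRUE)), "both outcome classes")
  d$y <- as.numeric(d$age_y > 30)  # perfectly separated by age
  expect_error(fit_logistic(model_input(d, "y", binary = TRUE)), "separation")
})

test_that("qq diagnostics behave at identity, symmetry and non-normality", {
  n <- 50
  theo <- qnorm((1:n - 0.5) / n)
  q <- qq_normality(theo)
  expect_equal(q$correlation, 1.0, tolerance = 1e-12)
  ## two-point residual distribution is far from normal
  r2 <- rep(c(-1, 1), 50)
  expect_lt(qq_normality(r2)$correlation, 0.95)
  ## sign flip leaves the correlation unchanged (normal quantiles are symmetric)
  set.seed(20)
  r <- rnorm(100)
  expect_equal(qq_normality(-r)$correlation, qq_normality(r)$correlation,
               tolerance = 1e-10)
  expect_error(qq_normality(rep(1, 10)), "constant")
  expect_error(qq_normality(c(1, 2)), "at least 3")
})

test_that("the results table carries one row per read-out with the right annotations", {
  d <- fake_table(60, 13)
  set.seed(14)
  d$y <- 1 + 0.2 * d$age_y + rnorm(60, 0, 3)
  d$z <- rbinom(60, 1, plogis(-2 + 0.1 * d$age_y))
  lin <- fit_linear(model_input(d, "y"))
  tab1 <- results_table(list(lin))
  expect_equal(nrow(tab1), 1)
  expect_identical(tab1$fit_stat_name, "R2")
  logi <- fit_logistic(model_input(d, "z", binary = TRUE))
  tab2 <- results_table(list(lin, logi))
  expect_equal(nrow(tab2), 2)
  expect_identical(tab2$fit_stat_name[tab2$model == "logistic"], "pseudo-R2")
  expect_match(attr(tab2, "text"), "pseudo-R2")
  expect_match(attr(tab2, "text"), "\\* p < 0.05")
})
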