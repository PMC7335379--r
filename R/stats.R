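#' Assemble a model input table for one read-out
#'
#' Covariate coding follows the inference layer's convention: male = 1,
#' semitendinosus = 1, intact = 1.
#'
#' @param data data.frame with columns `age_y`, `gender` (`"M"`/`"F"`),
#'   `tendon` (`"ST"`/`"G"`), plus the read-out column.
#' @param readout name of the read-out column.
#' @param binary is the read-out the binary intact indicator?
#' @return data.frame of class `model_input` with columns `value`, `age`,
#'   `male`, `semitend`; rows with a missing read-out are dropped (released
#'   micro-tissues carry `NA` biochemical read-outs).
#' @export
model_input <- function(data, readout, binary = FALSE) {
  stop_if(!all(c("age_y", "gender", "tendon", readout) %in% names(data)),
          "data must contain age_y, gender, tendon and '%s'", readout)
  out <- data.frame(value = data[[readout]],
                    age = data$age_y,
                    male = as.numeric(data$gender == "M"),
                    semitend = as.numeric(data$tendon == "ST"))
  stop_if(anyNA(out$age) || anyNA(out$male) || anyNA(out$semitend),
          "missing covariates are not allowed")
  out <- out[!is.na(out$value), , drop = FALSE]
  if (binary) stop_if(!all(out$value %in% c(0, 1)), "binary read-out must be 0/1")
  structure(out, readout = readout, binary = binary, class = c("model_input", "data.frame"))
}

regression_result <- function(readout, kind, coefs, fit_stat, fit_stat_name, n,
                              variant = "all") {
  structure(list(readout = readout, kind = kind, coefficients = coefs,
                 fit_stat = fit_stat, fit_stat_name = fit_stat_name,
                 n = n, alpha = 0.05, variant = variant),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<%s regression of %s (n = %d): %s = %.3g>\n",
              x$kind, x$readout, x$n, x$fit_stat_name, x$fit_stat))
  print(x$coefficients, digits = 3)
  invisible(x)
}

check_design_rank <- function(mm) {
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    dropped <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
}

coef_table <- function(sm_coef) {
  terms <- c("(Intercept)", "age", "male", "semitend")
  out <- data.frame(term = terms,
                    estimate = sm_coef[terms, 1],
                    std_error = sm_coef[terms, 2],
                    p_value = sm_coef[terms, 4],
                    row.names = NULL)
  out$significant <- out$p_value < 0.05
  out
}

#' Multiple linear regression of a continuous read-out
#'
#' Ordinary least squares of the read-out on age, gender and tendon type with
#' intercept; per-coefficient two-sided t-tests; multiple R-squared reported.
#' No multiple-testing correction is applied (one model per read-out,
#' alpha = 0.05 per test, recorded in the result).
#'
#' @param input a [model_input()].
#' @param variant label for the fitted sample (e.g. with/without flagged
#'   loading-control outliers).
#' @return a `regression_result`.
#' @export
fit_linear <- function(input, variant = "all") {
  stop_if(!inherits(input, "model_input"), "input must come from model_input()")
  n <- nrow(input)
  stop_if(n <= 4L, "need more rows (%d) than parameters (4)", n)
  mm <- cbind(`(Intercept)` = 1, age = input$age, male = input$male,
              semitend = input$semitend)
  check_design_rank(mm)
  fit <- lm(value ~ age + male + semitend, data = input)
  sm <- summary(fit)
  regression_result(attr(input, "readout"), "linear", coef_table(sm$coefficients),
                    sm$r.squared, "R2", n, variant)
}

#' Logistic regression of the intact/released outcome
#'
#' Maximum-likelihood logit fit (iteratively reweighted least squares,
#' coefficient tolerance 1e-8, at most 100 iterations) of the intact
#' indicator on age, gender and tendon type; Wald p-values; McFadden
#' pseudo-R-squared (1 - logLik(model)/logLik(intercept-only)).
#'
#' @inheritParams fit_linear
#' @return a `regression_result`.
#' @export
fit_logistic <- function(input, variant = "all") {
  stop_if(!inherits(input, "model_input"), "input must come from model_input()")
  stop_if(!isTRUE(attr(input, "binary")), "input must be built with binary = TRUE")
  n <- nrow(input)
  stop_if(length(unique(input$value)) < 2L, "both outcome classes must be present")
  mm <- cbind(`(Intercept)` = 1, age = input$age, male = input$male,
              semitend = input$semitend)
  check_design_rank(mm)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(value ~ age + male + semitend, family = binomial(),
        data = input, control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  ## diverging coefficients (relative to covariate scale) indicate separation
  scales <- pmax(apply(mm, 2, sd), .Machine$double.eps)
  scales[1] <- 1
  if (!fit$converged || (sep_warn && any(abs(coef(fit) * scales) > 10)))
    stop("perfect separation detected: coefficient estimates diverge", call. = FALSE)
  sm <- summary(fit)
  ll_model <- as.numeric(logLik(fit))
  ll_null <- as.numeric(logLik(glm(value ~ 1, family = binomial(), data = input)))
  pseudo_r2 <- 1 - ll_model / ll_null
  regression_result(attr(input, "readout"), "logistic", coef_table(sm$coefficients),
                    pseudo_r2, "pseudo-R2", n, variant)
}

#' Quantile-comparison (normal Q-Q) diagnostic
#'
#' Sample order statistics against standard-normal quantiles at probability
#' points `(i - 0.5)/n`, with the probability-plot correlation as a scalar
#' normality diagnostic.
#'
#' @param residuals numeric vector, length >= 3, non-constant.
#' @return list with `pairs` (data.frame `theoretical`, `sample`) and
#'   `correlation`.
#' @export
qq_normality <- function(residuals) {
  r <- residuals[!is.na(residuals)]
  stop_if(length(r) < 3L, "need at least 3 residuals")
  stop_if(sd(r) == 0, "constant residuals have no quantile spread")
  n <- length(r)
  theo <- qnorm((seq_len(n) - 0.5) / n)
  samp <- sort(r)
  list(pairs = data.frame(theoretical = theo, sample = samp),
       correlation = stats::cor(theo, samp))
}

#' Format a set of regression results as a per-read-out table
#'
#' One row per read-out with estimate / standard error / p-value per
#' covariate, significance stars at alpha = 0.05, and the fit statistic
#' (multiple R-squared, or McFadden pseudo-R-squared for the logistic row,
#' which is footnoted in the text rendering).
#'
#' @param results list of `regression_result` objects.
#' @return data.frame (one row per result) with attribute `text` holding a
#'   plain-text rendering.
#' @export
results_table <- function(results) {
  stop_if(length(results) == 0L, "need at least one regression result")
  if (inherits(results, "regression_result")) results <- list(results)
  star <- function(p) ifelse(p < 0.05, "*", "")
  rows <- lapply(results, function(r) {
    cf <- r$coefficients
    g <- function(term, col) cf[cf$term == term, col]
    data.frame(readout = r$readout, model = r$kind, n = r$n,
               variant = r$variant,
               age_estimate = g("age", "estimate"),
               age_se = g("age", "std_error"),
               age_p = g("age", "p_value"),
               age_sig = star(g("age", "p_value")),
               gender_estimate = g("male", "estimate"),
               gender_se = g("male", "std_error"),
               gender_p = g("male", "p_value"),
               gender_sig = star(g("male", "p_value")),
               tendon_estimate = g("semitend", "estimate"),
               tendon_se = g("semitend", "std_error"),
               tendon_p = g("semitend", "p_value"),
               tendon_sig = star(g("semitend", "p_value")),
               fit_stat = r$fit_stat,
               fit_stat_name = r$fit_stat_name,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  fmt <- function(x) formatC(x, digits = 3, format = "g")
  lines <- c(
    sprintf("%-28s %-9s %22s %22s %22s %10s", "read-out", "model",
            "age (years)", "gender (M = 1)", "tendon (ST = 1)", "fit"),
    sprintf("%-28s %-9s %22s %22s %22s %10s", "", "",
            "est (se) p", "est (se) p", "est (se) p", ""))
  for (i in seq_len(nrow(out))) {
    cell <- function(e, s, p, sg) sprintf("%s (%s) %s%s", fmt(e), fmt(s), fmt(p), sg)
    lines <- c(lines, sprintf("%-28s %-9s %22s %22s %22s %10s",
                              out$readout[i], out$model[i],
                              cell(out$age_estimate[i], out$age_se[i], out$age_p[i], out$age_sig[i]),
                              cell(out$gender_estimate[i], out$gender_se[i], out$gender_p[i], out$gender_sig[i]),
                              cell(out$tendon_estimate[i], out$tendon_se[i], out$tendon_p[i], out$tendon_sig[i]),
                              paste0(fmt(out$fit_stat[i]),
                                     ifelse(out$fit_stat_name[i] == "pseudo-R2", "^a", ""))))
  }
  lines <- c(lines, "* p < 0.05; alpha = 0.05 per test, no multiple-testing correction",
             "^a pseudo-R2 (McFadden), since multiple R2 is not defined for logistic regression")
  attr(out, "text") <- paste(lines, collapse = "\n")
  out
}
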