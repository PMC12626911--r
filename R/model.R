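# Covariate-adjusted linear regression of the procrastination outcome on
# ilr (pivot) coordinates of the 24-h behavior composition.

DURATION_COLS <- c(SLP = "slp_min", SB = "sb_min", LPA = "lpa_min",
                   MVPA = "mvpa_min")

# Pull the duration columns out of a subject table, replace zeros, close
# rows to the day total.
extract_compositions <- function(data, total = MINUTES_PER_DAY,
                                 zero_delta = 1) {
  miss <- setdiff(unname(DURATION_COLS), names(data))
  if (length(miss) > 0)
    stop("missing duration column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(data[, unname(DURATION_COLS)])
  colnames(m) <- names(DURATION_COLS)
  m <- replace_zeros(m, delta = zero_delta)
  close_comp(m, total = total)
}

# 0/1 coding for the default binary covariates; age is centered.
code_binary <- function(x, one_levels, name) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1)))
      stop("numeric covariate '", name, "' must be coded 0/1")
    return(as.numeric(x))
  }
  x <- as.character(x)
  out <- as.numeric(tolower(x) %in% one_levels)
  if (!all(tolower(x) %in% c(one_levels, c("male", "urban", "0"))) &&
      length(unique(x)) > 2)
    stop("covariate '", name, "' has more than two levels")
  out
}

code_covariates <- function(data, covariates, age_center = NULL) {
  if (length(covariates) == 0)
    return(list(X = matrix(nrow = nrow(data), ncol = 0), age_center = NA))
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0)
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  cols <- lapply(covariates, function(v) {
    x <- data[[v]]
    if (v == "gender") code_binary(x, c("female", "f", "1"), v)
    else if (v == "residence") code_binary(x, c("rural", "1"), v)
    else if (is.numeric(x)) x
    else stop("covariate '", v, "' must be numeric or a known binary coding")
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  if ("age" %in% covariates) {
    if (is.null(age_center)) age_center <- mean(X[, "age"])
    X[, "age"] <- X[, "age"] - age_center
  } else age_center <- NA_real_
  list(X = X, age_center = age_center)
}

build_design <- function(data, outcome, pivot_order, covariates,
                         total = MINUTES_PER_DAY, zero_delta = 1,
                         age_center = NULL) {
  if (!outcome %in% names(data)) stop("outcome column '", outcome, "' missing")
  comp <- extract_compositions(data, total = total, zero_delta = zero_delta)
  basis <- pivot_basis(pivot_order)
  Z <- ilr_coords(comp, basis)
  cov <- code_covariates(data, covariates, age_center = age_center)
  y <- data[[outcome]]
  if (!is.numeric(y)) stop("outcome must be numeric")
  X <- cbind(`(Intercept)` = 1, Z, cov$X)
  list(y = y, X = X, Z = Z, comp = comp, basis = basis,
       Xcov = cov$X, age_center = cov$age_center)
}

ols_fit <- function(y, X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qrx, y)
  res <- y - drop(X %*% coef)
  n <- length(y)
  df <- n - ncol(X)
  if (df < 1) stop("too few observations (n = ", n, ") for ",
                   ncol(X), " parameters")
  rss <- sum(res^2)
  sigma2 <- rss / df
  XtXinv <- matrix(0, ncol(X), ncol(X),
                   dimnames = list(colnames(X), colnames(X)))
  piv <- qrx$pivot
  XtXinv[piv, piv] <- chol2inv(qr.R(qrx))
  tss <- sum((y - mean(y))^2)
  list(coefficients = coef, residuals = res, sigma2 = sigma2,
       df_residual = df, vcov = sigma2 * XtXinv,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_)
}

#' Fit the compositional outcome model
#'
#' Ordinary least squares of a procrastination score on the D-1 ilr pivot
#' coordinates of the daily behavior composition plus covariates
#' (by default gender, age and residence; gender/residence as 0/1
#' indicators with female/rural = 1, age centered at its sample mean).
#' Fitted values, residuals, R-squared and predictions are invariant to the
#' pivot order; only the coefficient parameterization changes.
#'
#' @param data data.frame with duration columns `slp_min`, `sb_min`,
#'   `lpa_min`, `mvpa_min`, the covariates and the outcome.
#' @param outcome Name of the outcome column. Default `"ap_total"`.
#' @param pivot_order Behavior permutation defining the ilr basis.
#' @param covariates Character vector of covariate column names.
#' @param total Closure constant for the durations.
#' @param zero_delta Replacement for zero durations (minutes).
#' @return Object of class `coda_fit`: coefficients, covariance matrix,
#'   residual variance, R-squared, n, the pivot basis, the sample's
#'   compositional mean (`center`) and the covariate reference values at
#'   which adjusted predictions are anchored.
#' @seealso [predict_outcome()], [per_part_coefficient_table()],
#'   [substitution_effect()]
#' @export
fit_outcome_model <- function(data, outcome = "ap_total",
                              pivot_order = ap_behaviors,
                              covariates = c("gender", "age", "residence"),
                              total = MINUTES_PER_DAY, zero_delta = 1) {
  d <- build_design(data, outcome, pivot_order, covariates,
                    total = total, zero_delta = zero_delta)
  n <- length(d$y)
  if (n <= ncol(d$X) + 1)
    stop("n = ", n, " too small for ", ncol(d$X), " parameters")
  f <- ols_fit(d$y, d$X)
  covariate_reference <- if (ncol(d$Xcov) > 0) colMeans(d$Xcov) else numeric(0)
  structure(list(coefficients = f$coefficients, vcov = f$vcov,
                 sigma2 = f$sigma2, df_residual = f$df_residual,
                 r_squared = f$r_squared, n = n,
                 basis = d$basis, pivot_order = d$basis$order,
                 covariates = names(covariate_reference),
                 covariate_reference = covariate_reference,
                 age_center = d$age_center,
                 center = comp_mean(d$comp, total = total),
                 arithmetic_center = close_comp(colMeans(d$comp), total = total),
                 y_mean = mean(d$y), outcome = outcome, total = total),
            class = "coda_fit")
}

#' @export
print.coda_fit <- function(x, ...) {
  cat("Compositional outcome model (", x$outcome, "), n = ", x$n,
      ", R^2 = ", round(x$r_squared, 3), "\n", sep = "")
  cat("pivot order:", paste(x$pivot_order, collapse = " > "), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

# coefficient names of the ilr block
ilr_coef_names <- function(fit) rownames(fit$basis$contrast)

#' Predict the outcome at a composition
#'
#' Linear predictor of a [fit_outcome_model()] fit at a (re-closed)
#' composition, with covariates held at the fit's reference values (sample
#' means of the coded covariates) unless supplied.
#'
#' @param fit A `coda_fit`.
#' @param comp Named behavior composition (any positive total; it is closed).
#' @param covariates Optional named list/vector (`gender`, `age`,
#'   `residence`, coded as in the fit; `age` on the original scale).
#' @return Predicted outcome (numeric scalar, or vector if `comp` is a
#'   matrix).
#' @export
predict_outcome <- function(fit, comp, covariates = NULL) {
  stopifnot(inherits(fit, "coda_fit"))
  z <- ilr_coords(close_comp(comp, total = fit$total), fit$basis)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  cref <- fit$covariate_reference
  if (!is.null(covariates)) {
    covariates <- unlist(covariates)
    miss <- setdiff(fit$covariates, names(covariates))
    if (length(miss) > 0)
      stop("missing covariate value(s): ", paste(miss, collapse = ", "))
    cref <- covariates[fit$covariates]
    if ("age" %in% fit$covariates)
      cref["age"] <- cref["age"] - fit$age_center
  }
  X <- cbind(1, z,
             if (length(cref) > 0)
               matrix(cref, nrow(z), length(cref), byrow = TRUE))
  drop(X %*% fit$coefficients)
}

#' Per-behavior coefficient table
#'
#' Refits the outcome model once per behavior with that behavior leading the
#' pivot order and reports the first-coordinate coefficient - the effect of
#' increasing that behavior relative to the geometric mean of the other
#' three - with its t-based confidence interval and p-value. This is the
#' standard "one interpretable coefficient per part" presentation of
#' compositional regression.
#'
#' @inheritParams fit_outcome_model
#' @param conf_level Confidence level for the intervals.
#' @return data.frame with one row per behavior: `behavior`, `beta`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
per_part_coefficient_table <- function(data, outcome = "ap_total",
                                       covariates = c("gender", "age",
                                                      "residence"),
                                       total = MINUTES_PER_DAY,
                                       zero_delta = 1, conf_level = 0.95) {
  rows <- lapply(ap_behaviors, function(b) {
    fit <- fit_outcome_model(data, outcome = outcome,
                             pivot_order = c(b, setdiff(ap_behaviors, b)),
                             covariates = covariates, total = total,
                             zero_delta = zero_delta)
    cn <- ilr_coef_names(fit)[1]
    beta <- unname(fit$coefficients[cn])
    se <- sqrt(fit$vcov[cn, cn])
    tq <- stats::qt(1 - (1 - conf_level) / 2, fit$df_residual)
    data.frame(behavior = b, beta = beta,
               ci_low = beta - tq * se, ci_high = beta + tq * se,
               p_value = 2 * stats::pt(-abs(beta / se), fit$df_residual),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation screen
#'
#' Convenience summary: correlation of the outcome with each behavior's
#' daily proportion. Descriptive only; inference is done on ilr
#' coordinates.
#'
#' @inheritParams fit_outcome_model
#' @return data.frame with `behavior`, `r`, `p_value`.
#' @export
correlation_screen <- function(data, outcome = "ap_total",
                               total = MINUTES_PER_DAY, zero_delta = 1) {
  comp <- extract_compositions(data, total = total, zero_delta = zero_delta)
  y <- data[[outcome]]
  rows <- lapply(ap_behaviors, function(b) {
    ct <- stats::cor.test(comp[, b], y)
    data.frame(behavior = b, r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
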