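# Logistic-normal synthetic cohort generator. Compositions are drawn as
# multivariate normal ilr coordinates around a reference day and mapped
# back to the simplex; the outcome follows a linear model on the ilr
# coordinates plus covariates with Gaussian noise. Every generated dataset
# carries its ground truth so estimators can be scored exactly.

# Map from canonical-basis ilr coefficients to the four per-part
# (leading-pivot first-coordinate) coefficients. Row j is the unit vector
# r_j with per_part_beta[j] = r_j . beta_ilr.
per_part_map <- function() {
  B0 <- pivot_basis(ap_behaviors)$contrast
  M <- t(vapply(ap_behaviors, function(b) {
    Bj <- pivot_basis(c(b, setdiff(ap_behaviors, b)))$contrast
    drop(B0 %*% Bj[1, ])
  }, numeric(length(ap_behaviors) - 1)))
  rownames(M) <- ap_behaviors
  M
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic cohort: sample size, RNG seed, the
#' center composition, the spread of ilr coordinates, the true linear model
#' and the covariate mix. Defaults emulate a cohort of 986 college students:
#' the center is [ap_center_minutes], the diagonal ilr spread of 0.05 puts
#' all pairwise log-ratio variances at 0.10 (the order observed for such
#' cohorts), the covariate mix is 49.7% female / 54.4% rural / age
#' 20.6 +/- 2.1 years, covariate effects point female- and rural-higher,
#' and the noise is set so the population R-squared of the linear model is
#' `target_r2` (default 0.25).
#'
#' @param n Sample size.
#' @param seed Integer RNG seed.
#' @param center Named center composition (minutes).
#' @param ilr_spread (D-1)x(D-1) positive-definite covariance of the ilr
#'   coordinates (canonical pivot basis).
#' @param beta_ilr True coefficients of the canonical-basis ilr
#'   coordinates. Default: least-squares match to per-part coefficients
#'   (SLP 1.95, SB 2.78, LPA 2.05, MVPA -3.21); because the four per-part
#'   coefficients of a linear compositional model always sum to zero, the
#'   planted values are the closest sum-zero quadruple.
#' @param beta_cov Named covariate effects `(gender, age, residence)` on
#'   the score, gender/residence as female/rural = 1 indicators.
#' @param mean_outcome Population mean of the outcome (sets the intercept).
#' @param noise_sd Residual SD; if `NULL`, derived from `target_r2`.
#' @param target_r2 Population explained variance used when `noise_sd` is
#'   `NULL`.
#' @param covariate_mix List: `p_female`, `p_rural`, `age_mean`, `age_sd`.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n = 986, seed = 1L,
                             center = ap_center_minutes,
                             ilr_spread = diag(0.05, 3),
                             beta_ilr = NULL,
                             beta_cov = c(gender = 3.4, age = 0.2,
                                          residence = 3.7),
                             mean_outcome = 57.8,
                             noise_sd = NULL, target_r2 = 0.25,
                             covariate_mix = list(p_female = 490 / 986,
                                                  p_rural = 536 / 986,
                                                  age_mean = 20.6,
                                                  age_sd = 2.1)) {
  stopifnot(n >= 1, length(seed) == 1)
  center <- close_comp(center, total = MINUTES_PER_DAY)
  d <- length(ap_behaviors) - 1
  stopifnot(is.matrix(ilr_spread), nrow(ilr_spread) == d,
            ncol(ilr_spread) == d)
  if (any(abs(ilr_spread - t(ilr_spread)) > 1e-12) ||
      any(eigen(ilr_spread, symmetric = TRUE,
                only.values = TRUE)$values <= 0))
    stop("ilr_spread must be symmetric positive definite")
  if (is.null(beta_ilr)) {
    targets <- c(SLP = 1.95, SB = 2.78, LPA = 2.05, MVPA = -3.21)
    beta_ilr <- drop(qr.solve(per_part_map(), targets))  # least squares
  }
  stopifnot(length(beta_ilr) == d)
  cfg <- structure(list(n = as.integer(n), seed = as.integer(seed),
                        center = center, ilr_spread = ilr_spread,
                        beta_ilr = unname(beta_ilr), beta_cov = beta_cov,
                        mean_outcome = mean_outcome, noise_sd = noise_sd,
                        covariate_mix = covariate_mix),
                   class = "generator_config")
  if (is.null(noise_sd)) {
    stopifnot(target_r2 > 0, target_r2 < 1)
    cfg <- calibrate_explained_variance(cfg, target_r2)
  } else stopifnot(noise_sd > 0)
  cfg
}

# variance of the true linear predictor under the config's population
signal_variance <- function(config) {
  b <- config$beta_ilr
  v <- drop(t(b) %*% config$ilr_spread %*% b)
  cm <- config$covariate_mix
  bc <- config$beta_cov
  v + bc[["gender"]]^2 * cm$p_female * (1 - cm$p_female) +
    bc[["residence"]]^2 * cm$p_rural * (1 - cm$p_rural) +
    bc[["age"]]^2 * cm$age_sd^2
}

#' Population explained variance of a configuration
#'
#' @param config A [generator_config()].
#' @return Fraction of outcome variance explained by the true linear
#'   predictor.
#' @export
population_r2 <- function(config) {
  vs <- signal_variance(config)
  vs / (vs + config$noise_sd^2)
}

true_intercept <- function(config) {
  cm <- config$covariate_mix
  z0 <- ilr_coords(config$center)
  config$mean_outcome - sum(config$beta_ilr * z0) -
    config$beta_cov[["gender"]] * cm$p_female -
    config$beta_cov[["residence"]] * cm$p_rural -
    config$beta_cov[["age"]] * cm$age_mean
}

#' True substitution effect implied by a configuration
#'
#' Exact model-implied outcome change for a donor-to-recipient reallocation
#' at the config's center composition.
#'
#' @param config A [generator_config()].
#' @param donor,recipient,minutes Reallocation specification.
#' @return Numeric delta (score units).
#' @export
true_substitution_effect <- function(config, donor, recipient, minutes) {
  dz <- ilr_coords(reallocate(config$center, donor, recipient, minutes)) -
    ilr_coords(config$center)
  sum(config$beta_ilr * dz)
}

#' True per-part coefficients implied by a configuration
#'
#' @param config A [generator_config()].
#' @return Named vector: the leading-pivot first-coordinate coefficient for
#'   each behavior.
#' @export
true_per_part_beta <- function(config) {
  drop(per_part_map() %*% config$beta_ilr)
}

#' Generate a synthetic cohort
#'
#' Draws `config$n` subjects: ilr coordinates from
#' `MVN(ilr(center), ilr_spread)` mapped back to minutes (logistic-normal
#' compositions closing to 1440), Bernoulli gender/residence and Gaussian
#' age, and the outcome from the true linear model plus `N(0, noise_sd)`
#' noise. Fully reproducible from the config's seed.
#'
#' @param config A [generator_config()].
#' @param seed Optional override of `config$seed`.
#' @return List of class `synthetic_cohort`: `data` (data.frame with
#'   `slp_min`, `sb_min`, `lpa_min`, `mvpa_min`, `gender`, `age`,
#'   `residence`, `ap_total`) and `truth` (config echo plus intercept,
#'   per-part betas, all 15-min substitution effects at the center, and the
#'   population R-squared).
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  n <- config$n
  z0 <- ilr_coords(config$center)
  Z <- MASS::mvrnorm(n, mu = z0, Sigma = config$ilr_spread)
  if (n == 1) Z <- matrix(Z, nrow = 1)
  comp <- ilr_inverse(Z, total = MINUTES_PER_DAY)
  cm <- config$covariate_mix
  gender <- stats::rbinom(n, 1, cm$p_female)      # 1 = female
  residence <- stats::rbinom(n, 1, cm$p_rural)    # 1 = rural
  age <- stats::rnorm(n, cm$age_mean, cm$age_sd)
  eta <- true_intercept(config) + drop(Z %*% config$beta_ilr) +
    config$beta_cov[["gender"]] * gender +
    config$beta_cov[["residence"]] * residence +
    config$beta_cov[["age"]] * age
  y <- eta + stats::rnorm(n, 0, config$noise_sd)
  data <- data.frame(slp_min = comp[, "SLP"], sb_min = comp[, "SB"],
                     lpa_min = comp[, "LPA"], mvpa_min = comp[, "MVPA"],
                     gender = gender, age = age, residence = residence,
                     ap_total = y)
  subs <- substitution_truth(config, minutes = 15)
  truth <- list(config = config, seed_used = seed,
                intercept = true_intercept(config),
                per_part_beta = true_per_part_beta(config),
                substitution_effects_15min = subs,
                population_r2 = population_r2(config))
  structure(list(data = data, truth = truth), class = "synthetic_cohort")
}

substitution_truth <- function(config, minutes = 15) {
  rows <- list()
  for (donor in ap_behaviors)
    for (recipient in setdiff(ap_behaviors, donor))
      rows[[length(rows) + 1]] <- data.frame(
        donor = donor, recipient = recipient, minutes = minutes,
        delta = true_substitution_effect(config, donor, recipient, minutes),
        stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort: n =", nrow(x$data),
      "| population R^2 =", round(x$truth$population_r2, 3), "\n")
  invisible(x)
}

#' Calibrate a planted substitution effect
#'
#' Adjusts the true ilr coefficient vector along the ilr-difference
#' direction of the given reallocation so that the exact model-implied
#' effect at the center equals `target`. All components of the coefficient
#' vector orthogonal to that direction are untouched.
#'
#' @param config A [generator_config()].
#' @param target Desired model-implied outcome change (score units; negative
#'   = the reallocation lowers the score).
#' @param donor,recipient,minutes Reallocation defining the planted effect.
#' @return Updated `generator_config`.
#' @export
calibrate_effect <- function(config, target, donor, recipient, minutes) {
  stopifnot(inherits(config, "generator_config"))
  dz <- ilr_coords(reallocate(config$center, donor, recipient, minutes)) -
    ilr_coords(config$center)
  nrm2 <- sum(dz^2)
  if (nrm2 < 1e-14) stop("degenerate reallocation: zero ilr displacement")
  b <- config$beta_ilr
  config$beta_ilr <- b + (target - sum(b * dz)) / nrm2 * dz
  config
}

#' Calibrate a planted per-part coefficient
#'
#' Sets the true leading-pivot first-coordinate coefficient for one
#' behavior to `target` exactly, leaving the orthogonal components of the
#' coefficient vector unchanged.
#'
#' @param config A [generator_config()].
#' @param behavior One of [ap_behaviors].
#' @param target Desired coefficient (score units per ilr unit).
#' @return Updated `generator_config`.
#' @export
calibrate_coefficient <- function(config, behavior, target) {
  stopifnot(inherits(config, "generator_config"),
            behavior %in% ap_behaviors)
  r <- per_part_map()[behavior, ]      # unit vector
  b <- config$beta_ilr
  config$beta_ilr <- b + (target - sum(b * r)) * r
  config
}

#' Calibrate the population explained variance
#'
#' Sets `noise_sd` so that the population R-squared of the true linear
#' model (given the config's predictor distribution) equals `target_r2`.
#'
#' @param config A [generator_config()].
#' @param target_r2 Desired explained variance in (0, 1).
#' @return Updated `generator_config`.
#' @export
calibrate_explained_variance <- function(config, target_r2) {
  stopifnot(inherits(config, "generator_config"),
            target_r2 > 0, target_r2 < 1)
  vs <- signal_variance(config)
  if (vs <= 0) stop("configuration has zero signal variance")
  config$noise_sd <- sqrt(vs * (1 - target_r2) / target_r2)
  config
}

#' Generate PASS item responses reproducing requested totals
#'
#' Builds item-level ratings whose [score_pass()] totals (and, optionally,
#' expectation subscores) match the requested values exactly - useful for
#' round-trip testing of the scoring pipeline. Infeasible requests are
#' clamped to the nearest attainable value with a warning.
#'
#' @param totals Integer vector of requested total scores (12-60 each).
#' @param expectations Optional integer vector of requested expectation
#'   subscores (6-30 each); default mid-scale 18.
#' @param seed Optional RNG seed (the allocation of points to items is
#'   randomized).
#' @return List of 6 x 3 rating matrices, one per requested total.
#' @export
generate_pass_items <- function(totals, expectations = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(expectations)) expectations <- rep(18L, length(totals))
  stopifnot(length(expectations) == length(totals))
  clamp <- function(x, lo, hi, what) {
    out <- pmin(pmax(round(x), lo), hi)
    if (any(out != x))
      warning("infeasible ", what, " clamped to [", lo, ", ", hi, "]")
    out
  }
  totals <- clamp(totals, 12L, 60L, "total")
  expectations <- clamp(expectations, 6L, 30L, "expectation")
  spread_points <- function(points, cells) {
    # distribute `points` unit increments over `cells` ratings capped at +4
    add <- integer(cells)
    while (points > 0) {
      open <- which(add < 4L)
      pick <- if (length(open) == 1) open else sample(open, 1)
      inc <- min(4L - add[pick], points)
      add[pick] <- add[pick] + inc
      points <- points - inc
    }
    add
  }
  lapply(seq_along(totals), function(i) {
    r <- matrix(1L, PASS_AREAS, 3)
    r[, 1:2] <- r[, 1:2] + spread_points(totals[i] - 12L, 2L * PASS_AREAS)
    r[, 3] <- r[, 3] + spread_points(expectations[i] - 6L, PASS_AREAS)
    r
  })
}
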