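# Isotemporal substitution: model-predicted change in the outcome when t
# minutes move from a donor behavior to a recipient behavior, the rest of
# the day held fixed.

#' Reallocate minutes between two behaviors
#'
#' @param comp Named composition (minutes).
#' @param donor Behavior losing `minutes`.
#' @param recipient Behavior gaining `minutes`.
#' @param minutes Nonnegative duration to move; must be strictly less than
#'   the donor's duration.
#' @return The reallocated composition (same total).
#' @export
reallocate <- function(comp, donor, recipient, minutes) {
  stopifnot(donor %in% ap_behaviors, recipient %in% ap_behaviors)
  if (donor == recipient) stop("donor and recipient must differ")
  if (minutes < 0) stop("minutes must be nonnegative")
  if (minutes >= comp[donor])
    stop("cannot move ", minutes, " min out of ", donor,
         ": only ", round(comp[donor], 2), " min available")
  out <- comp
  out[donor] <- out[donor] - minutes
  out[recipient] <- out[recipient] + minutes
  out
}

#' Predicted outcome change for one time reallocation
#'
#' Difference between the model prediction at the reallocated reference
#' composition and at the reference itself, covariates held at the fit's
#' reference values ("adjusted" prediction). A negative delta means the
#' reallocation is associated with a lower procrastination score.
#'
#' @param fit A [fit_outcome_model()] fit.
#' @param reference Reference composition (minutes). Default: the fit
#'   sample's compositional (geometric) mean; its closed arithmetic mean is
#'   available as `fit$arithmetic_center`.
#' @param donor,recipient Behavior labels (donor loses time).
#' @param minutes Minutes reallocated (default 15).
#' @param ci_method `"delta"` (t-interval via the delta method, default),
#'   `"bootstrap"` (requires `data`; see [bootstrap_ci()]) or `"none"`.
#' @param data Subject table, needed only for the bootstrap.
#' @param B,seed Bootstrap replicates and RNG seed.
#' @param conf_level Confidence level.
#' @return One-row data.frame: `donor`, `recipient`, `minutes`, `delta`,
#'   `ci_low`, `ci_high`, `method`.
#' @export
substitution_effect <- function(fit, reference = NULL, donor, recipient,
                                minutes = 15,
                                ci_method = c("delta", "bootstrap", "none"),
                                data = NULL, B = 1000, seed = NULL,
                                conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(fit, "coda_fit"))
  if (is.null(reference)) reference <- fit$center
  reference <- close_comp(reference, total = fit$total)
  new <- reallocate(reference, donor, recipient, minutes)
  delta <- predict_outcome(fit, new) - predict_outcome(fit, reference)
  if (ci_method == "delta") {
    dz <- ilr_coords(new, fit$basis) - ilr_coords(reference, fit$basis)
    cn <- ilr_coef_names(fit)
    v <- drop(t(dz) %*% fit$vcov[cn, cn] %*% dz)
    tq <- stats::qt(1 - (1 - conf_level) / 2, fit$df_residual)
    ci <- delta + c(-1, 1) * tq * sqrt(max(v, 0))
  } else if (ci_method == "bootstrap") {
    if (is.null(data)) stop("bootstrap CI needs the subject data")
    ci <- bootstrap_ci(data, donor = donor, recipient = recipient,
                       minutes = minutes, B = B, seed = seed,
                       outcome = fit$outcome,
                       pivot_order = fit$pivot_order,
                       covariates = fit$covariates,
                       reference = reference, conf_level = conf_level,
                       total = fit$total)
  } else ci <- c(NA_real_, NA_real_)
  data.frame(donor = donor, recipient = recipient, minutes = minutes,
             delta = delta, ci_low = ci[1], ci_high = ci[2],
             method = ci_method, stringsAsFactors = FALSE)
}

#' All-pairs 15-minute substitution table
#'
#' One row per ordered donor/recipient pair (12 rows for four behaviors),
#' grouped by donor in canonical behavior order.
#'
#' @inheritParams substitution_effect
#' @return data.frame of [substitution_effect()] rows.
#' @export
substitution_table <- function(fit, reference = NULL, minutes = 15,
                               ci_method = c("delta", "bootstrap", "none"),
                               data = NULL, B = 1000, seed = NULL,
                               conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  rows <- list()
  for (donor in ap_behaviors)
    for (recipient in setdiff(ap_behaviors, donor))
      rows[[length(rows) + 1]] <-
        substitution_effect(fit, reference, donor, recipient, minutes,
                            ci_method = ci_method, data = data, B = B,
                            seed = seed, conf_level = conf_level)
  do.call(rbind, rows)
}

#' Dose-response curves along reallocation paths
#'
#' Predicted outcome change as a function of reallocated minutes for each
#' donor/recipient pair, with a pointwise confidence band (delta method).
#' Grid points that are infeasible (the donor would run out of time) are
#' dropped with a note, not an error.
#'
#' @inheritParams substitution_effect
#' @param pairs Optional data.frame with `donor` and `recipient` columns;
#'   default all 12 ordered pairs.
#' @param grid Increasing vector of minutes. Default 5-60 by 5.
#' @return Tidy data.frame: `donor`, `recipient`, `minutes`, `delta`,
#'   `ci_low`, `ci_high`.
#' @export
dose_response_curves <- function(fit, reference = NULL, pairs = NULL,
                                 grid = seq(5, 60, by = 5),
                                 conf_level = 0.95) {
  stopifnot(all(diff(grid) > 0), all(grid > 0))
  if (is.null(reference)) reference <- fit$center
  reference <- close_comp(reference, total = fit$total)
  if (is.null(pairs)) {
    pairs <- expand.grid(recipient = ap_behaviors, donor = ap_behaviors,
                         stringsAsFactors = FALSE)[, c("donor", "recipient")]
    pairs <- pairs[pairs$donor != pairs$recipient, ]
  }
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    donor <- pairs$donor[k]; recipient <- pairs$recipient[k]
    ok <- grid < reference[donor]
    if (!all(ok))
      message("dose_response_curves: ", donor, "->", recipient,
              " truncated at ", round(reference[donor], 1), " min")
    for (t in grid[ok])
      rows[[length(rows) + 1]] <-
        substitution_effect(fit, reference, donor, recipient, t,
                            ci_method = "delta", conf_level = conf_level)
  }
  out <- do.call(rbind, rows)
  out[, c("donor", "recipient", "minutes", "delta", "ci_low", "ci_high")]
}

#' Nonparametric bootstrap CI for a substitution effect
#'
#' Percentile interval of the predicted change over B resamples of subjects
#' (refitting the outcome model each time). The reference composition and
#' covariate anchor are held at their full-sample values so the interval
#' reflects coefficient uncertainty at a fixed, interpretable reference.
#' Rank-deficient resamples are redrawn (with a note).
#'
#' @param data Subject table as in [fit_outcome_model()].
#' @param donor,recipient,minutes Reallocation specification.
#' @param B Number of resamples (>= 100).
#' @param seed RNG seed; the interval is reproducible given the seed.
#' @param outcome,pivot_order,covariates,total Passed to the refits.
#' @param reference Reference composition; default the full-sample
#'   compositional mean.
#' @param conf_level Confidence level.
#' @return Numeric `c(ci_low, ci_high)` with attribute `"boot_deltas"`.
#' @export
bootstrap_ci <- function(data, donor, recipient, minutes, B = 1000,
                         seed = NULL, outcome = "ap_total",
                         pivot_order = ap_behaviors,
                         covariates = c("gender", "age", "residence"),
                         reference = NULL, conf_level = 0.95,
                         total = MINUTES_PER_DAY) {
  if (B < 100) stop("B must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  full <- fit_outcome_model(data, outcome = outcome,
                            pivot_order = pivot_order,
                            covariates = covariates, total = total)
  if (is.null(reference)) reference <- full$center
  reference <- close_comp(reference, total = total)
  new <- reallocate(reference, donor, recipient, minutes)
  dz <- ilr_coords(new, full$basis) - ilr_coords(reference, full$basis)
  # design pieces are rebuilt per resample from the raw table
  d <- build_design(data, outcome, pivot_order, covariates, total = total,
                    age_center = full$age_center)
  n <- length(d$y)
  cn <- ilr_coef_names(full)
  deltas <- numeric(B)
  redrawn <- 0
  b <- 1
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- d$X[idx, , drop = FALSE]
    qrb <- qr(Xb)
    if (qrb$rank < ncol(Xb)) { redrawn <- redrawn + 1; next }
    cf <- qr.coef(qrb, d$y[idx])
    deltas[b] <- sum(cf[cn] * dz)
    b <- b + 1
  }
  if (redrawn > 0)
    message("bootstrap_ci: redrew ", redrawn, " rank-deficient resample(s)")
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(deltas, c(a, 1 - a)))
  attr(ci, "boot_deltas") <- deltas
  ci
}

#' Penalized-spline dose-response model
#'
#' Generalized additive model of the outcome on covariates plus penalized
#' cubic regression spline smooths of the D-1 ilr coordinates (basis
#' dimension `k` per smooth, smoothing parameters by generalized
#' cross-validation). Substitution curves are obtained by predicting along
#' each reallocation path from the reference composition. If the smoothing
#' search fails to converge the model falls back to unpenalized smooths
#' with fixed degrees of freedom `k - 1`, with a warning.
#'
#' @inheritParams fit_outcome_model
#' @param k Basis dimension per smooth (default 5).
#' @param pairs,grid,reference,conf_level As in [dose_response_curves()].
#' @return List of class `coda_gam`: `gam` (the mgcv fit),
#'   `deviance_explained` (fraction in `[0, 1]`), `edf` (total effective df
#'   of the smooths), `curves` (tidy data.frame as in
#'   [dose_response_curves()]) and `fallback` (logical).
#' @export
spline_dose_response <- function(data, outcome = "ap_total",
                                 pivot_order = ap_behaviors,
                                 covariates = c("gender", "age", "residence"),
                                 k = 5, pairs = NULL,
                                 grid = seq(5, 60, by = 5),
                                 reference = NULL, conf_level = 0.95,
                                 total = MINUTES_PER_DAY, zero_delta = 1) {
  d <- build_design(data, outcome, pivot_order, covariates,
                    total = total, zero_delta = zero_delta)
  nz <- ncol(d$Z)
  if (length(d$y) <= k * nz + ncol(d$Xcov) + 1)
    stop("too few observations for ", nz, " smooth terms of dimension ", k)
  df <- data.frame(.y = d$y, d$Z, d$Xcov, check.names = TRUE)
  znames <- colnames(d$Z)
  smooths <- paste0("s(", znames, ", bs = \"cr\", k = ", k, ")")
  rhs <- paste(c(smooths, colnames(d$Xcov)), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  fallback <- FALSE
  g <- tryCatch(
    mgcv::gam(fml, data = df, method = "GCV.Cp"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(g) || !g$converged) {
    warning("GCV smoothing search did not converge; ",
            "falling back to fixed-df smooths")
    fallback <- TRUE
    smooths <- paste0("s(", znames, ", bs = \"cr\", k = ", k,
                      ", fx = TRUE)")
    rhs <- paste(c(smooths, colnames(d$Xcov)), collapse = " + ")
    g <- mgcv::gam(stats::as.formula(paste(".y ~", rhs)), data = df)
  }
  dev_expl <- summary(g)$dev.expl
  if (is.null(reference)) reference <- comp_mean(d$comp, total = total)
  reference <- close_comp(reference, total = total)
  cref <- if (ncol(d$Xcov) > 0) colMeans(d$Xcov) else numeric(0)

  gam_newdata <- function(comps) {
    z <- ilr_coords(comps, d$basis)
    if (is.null(dim(z))) z <- matrix(z, nrow = 1)
    nd <- data.frame(z)
    names(nd) <- znames
    for (v in names(cref)) nd[[v]] <- cref[[v]]
    nd
  }
  if (is.null(pairs)) {
    pairs <- expand.grid(recipient = ap_behaviors, donor = ap_behaviors,
                         stringsAsFactors = FALSE)[, c("donor", "recipient")]
    pairs <- pairs[pairs$donor != pairs$recipient, ]
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  Xref <- mgcv::predict.gam(g, gam_newdata(matrix(reference, nrow = 1,
                                                  dimnames = list(NULL, names(reference)))),
                            type = "lpmatrix")
  rows <- list()
  for (kk in seq_len(nrow(pairs))) {
    donor <- pairs$donor[kk]; recipient <- pairs$recipient[kk]
    ts <- grid[grid < reference[donor]]
    if (length(ts) < length(grid))
      message("spline_dose_response: ", donor, "->", recipient,
              " truncated at ", round(reference[donor], 1), " min")
    if (length(ts) == 0) next
    comps <- t(vapply(ts, function(t)
      reallocate(reference, donor, recipient, t), reference))
    Xp <- mgcv::predict.gam(g, gam_newdata(comps), type = "lpmatrix")
    Dx <- sweep(Xp, 2, Xref[1, ])
    delta <- drop(Dx %*% stats::coef(g))
    se <- sqrt(pmax(rowSums((Dx %*% g$Vp) * Dx), 0))
    rows[[length(rows) + 1]] <- data.frame(
      donor = donor, recipient = recipient, minutes = ts, delta = delta,
      ci_low = delta - zq * se, ci_high = delta + zq * se,
      stringsAsFactors = FALSE)
  }
  structure(list(gam = g, deviance_explained = dev_expl,
                 edf = sum(g$edf), curves = do.call(rbind, rows),
                 fallback = fallback, reference = reference),
            class = "coda_gam")
}

#' @export
print.coda_gam <- function(x, ...) {
  cat("Penalized-spline dose-response model: deviance explained = ",
      round(100 * x$deviance_explained, 1), "%",
      if (x$fallback) " (fixed-df fallback)", "\n", sep = "")
  invisible(x)
}
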