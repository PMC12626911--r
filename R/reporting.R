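# Descriptive tables, group tests, CSV I/O and the end-to-end pipeline.

#' Read a subject-level time-use CSV
#'
#' Expects one row per subject with columns `slp_min`, `sb_min`, `lpa_min`,
#' `mvpa_min` plus pass-through covariate/outcome columns (UTF-8, header
#' required). Zero durations are replaced ([replace_zeros()]) and rows are
#' renormalized to 1440 minutes; rows whose raw total deviates from 1440 by
#' more than `tol` (fractional) are counted and reported.
#'
#' @param path CSV file path.
#' @param zero_delta Replacement for zero durations (minutes).
#' @param tol Fractional deviation from 1440 beyond which a row is flagged.
#' @return data.frame with closed duration columns; attributes
#'   `n_replaced` and `n_flagged` record the cleaning counts.
#' @export
read_timeuse_csv <- function(path, zero_delta = 1, tol = 0.1) {
  data <- utils::read.csv(path, fileEncoding = "UTF-8")
  miss <- setdiff(unname(DURATION_COLS), names(data))
  if (length(miss) > 0)
    stop("missing duration column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(data[, unname(DURATION_COLS)])
  colnames(m) <- names(DURATION_COLS)
  raw_tot <- rowSums(m)
  n_flagged <- sum(abs(raw_tot / MINUTES_PER_DAY - 1) > tol)
  if (n_flagged > 0)
    message("read_timeuse_csv: ", n_flagged, " record(s) deviate from ",
            MINUTES_PER_DAY, " min by more than ", 100 * tol,
            "%; renormalized by closure")
  m <- replace_zeros(m, delta = zero_delta)
  n_replaced <- attr(m, "n_replaced")
  m <- close_comp(m, total = MINUTES_PER_DAY)
  data[, unname(DURATION_COLS)] <- m[, names(DURATION_COLS)]
  attr(data, "n_replaced") <- n_replaced
  attr(data, "n_flagged") <- n_flagged
  data
}

#' Descriptive statistics with a group test
#'
#' Per-group n, mean and SD of a continuous outcome with a one-way ANOVA F
#' test (classic equal-variance F), or a chi-square test (no continuity
#' correction by default) when the outcome itself is categorical/logical.
#' With a single group, descriptives are returned and the test omitted.
#'
#' @param data Subject table.
#' @param characteristic Grouping column name.
#' @param outcome Outcome column name (numeric, or categorical for the
#'   chi-square path).
#' @param correct Apply Yates continuity correction to the chi-square test.
#' @return List of class `descriptive_table`: `rows` (characteristic,
#'   group, n, mean, sd), `test_kind`, `statistic`, `df`, `p_value`.
#' @export
descriptive_table <- function(data, characteristic, outcome = "ap_total",
                              correct = FALSE) {
  stopifnot(characteristic %in% names(data), outcome %in% names(data))
  g <- factor(data[[characteristic]])
  y <- data[[outcome]]
  categorical <- !is.numeric(y)
  if (categorical) {
    tab <- table(g, factor(y))
    rows <- data.frame(characteristic = characteristic,
                       group = rownames(tab), n = as.integer(rowSums(tab)),
                       mean = NA_real_, sd = NA_real_,
                       stringsAsFactors = FALSE)
  } else {
    rows <- data.frame(
      characteristic = characteristic,
      group = levels(g),
      n = as.integer(table(g)),
      mean = as.numeric(tapply(y, g, mean)),
      sd = as.numeric(tapply(y, g, stats::sd)),
      stringsAsFactors = FALSE)
  }
  if (nlevels(g) < 2) {
    message("descriptive_table: single group; test omitted")
    out <- list(rows = rows, test_kind = "none", statistic = NA_real_,
                df = NA_real_, p_value = NA_real_)
  } else if (categorical) {
    ct <- stats::chisq.test(tab, correct = correct)
    out <- list(rows = rows, test_kind = "chi_square",
                statistic = unname(ct$statistic), df = unname(ct$parameter),
                p_value = ct$p.value)
  } else {
    a <- stats::anova(stats::lm(y ~ g))
    out <- list(rows = rows, test_kind = "anova",
                statistic = a$`F value`[1], df = a$Df[1],
                p_value = a$`Pr(>F)`[1])
  }
  structure(out, class = "descriptive_table")
}

#' @export
print.descriptive_table <- function(x, ...) {
  print(x$rows, row.names = FALSE)
  if (x$test_kind != "none")
    cat(x$test_kind, "statistic =", round(x$statistic, 2),
        " p =", format.pval(x$p_value), "\n")
  invisible(x)
}

write_rounded_csv <- function(df, path, digits = 2) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) a cohort, derive severity categories, produce the
#' descriptive table, fit the compositional outcome model, build the
#' per-behavior coefficient table, the all-pairs substitution table and the
#' dose-response curves (linear and penalized-spline), and write every
#' artifact plus a JSON run manifest to `out_dir`. Any stage failure aborts
#' with the stage name; partial outputs are removed.
#'
#' @param config Either a [generator_config()] (the cohort is simulated),
#'   the path to a subject CSV, or the path to a YAML file with fields
#'   `input_csv` or generator settings (`n`, `seed`) plus options
#'   (`minutes`, `ci_method`, `reference`).
#' @param out_dir Output directory (created if needed).
#' @param minutes Substitution duration for the table.
#' @param ci_method CI method for the substitution table.
#' @param reference `"geometric"` (compositional mean, default) or
#'   `"arithmetic"` (closed arithmetic mean).
#' @param seed Optional seed override.
#' @return Invisible list with every computed artifact.
#' @export
run_pipeline <- function(config, out_dir, minutes = 15,
                         ci_method = c("delta", "bootstrap", "none"),
                         reference = c("geometric", "arithmetic"),
                         seed = NULL) {
  ci_method <- match.arg(ci_method)
  reference <- match.arg(reference)
  if (is.character(config) && grepl("\\.ya?ml$", config)) {
    y <- yaml::read_yaml(config)
    if (!is.null(y$minutes)) minutes <- y$minutes
    if (!is.null(y$ci_method)) ci_method <- y$ci_method
    if (!is.null(y$reference)) reference <- y$reference
    if (!is.null(y$seed) && is.null(seed)) seed <- y$seed
    config <- if (!is.null(y$input_csv)) y$input_csv
              else do.call(generator_config,
                           y[intersect(names(y),
                                       names(formals(generator_config)))])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name, digits = 2) {
    path <- file.path(out_dir, name)
    write_rounded_csv(df, path, digits = digits)
    written <<- c(written, path)
    path
  }
  stage <- "load"
  res <- tryCatch({
    truth <- NULL
    if (inherits(config, "generator_config")) {
      stage <- "simulate"
      cohort <- generate_cohort(config, seed = seed)
      data <- cohort$data
      truth <- cohort$truth
      seed_used <- cohort$truth$seed_used
    } else {
      data <- read_timeuse_csv(config)
      seed_used <- seed
    }
    n0 <- nrow(data)
    message("pipeline: ", n0, " subject(s) after cleaning")

    stage <- "score"
    cat_total <- pmin(pmax(round(data$ap_total), 12), 60)
    data$category <- classify_procrastination(cat_total)
    data$chronic <- data$category %in% c("moderate", "severe")

    stage <- "describe"
    desc <- lapply(intersect(c("gender", "residence", "chronic"),
                             names(data)),
                   function(v) descriptive_table(data, v))
    desc_rows <- do.call(rbind, lapply(desc, function(d) {
      d$rows$test_kind <- d$test_kind
      d$rows$statistic <- d$statistic
      d$rows$p_value <- d$p_value
      d$rows
    }))
    emit(desc_rows, "descriptives.csv")

    stage <- "fit"
    fit <- fit_outcome_model(data)
    ref <- if (reference == "geometric") fit$center else
      fit$arithmetic_center
    ppt <- per_part_coefficient_table(data)
    emit(ppt, "per_part_coefficients.csv")

    stage <- "substitute"
    sub <- substitution_table(fit, reference = ref, minutes = minutes,
                              ci_method = ci_method, data = data,
                              seed = seed_used)
    emit(sub, "substitution_table.csv")

    stage <- "dose-response"
    curves <- dose_response_curves(fit, reference = ref)
    emit(curves, "dose_response_curves.csv")
    gam_fit <- spline_dose_response(data, reference = ref)
    emit(gam_fit$curves, "spline_dose_response_curves.csv")

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("procoda")),
      r_version = R.version.string,
      n = n0, seed = seed_used, minutes = minutes,
      ci_method = ci_method, reference_kind = reference,
      reference = as.list(ref), model_r2 = fit$r_squared,
      gam_deviance_explained = gam_fit$deviance_explained,
      prevalence_chronic = prevalence_chronic(data$category),
      outputs = basename(written))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, manifest_path)
    list(data = data, truth = truth, descriptives = desc, fit = fit,
         per_part = ppt, substitution = sub, curves = curves,
         gam = gam_fit, manifest = manifest, files = written)
  }, error = function(e) {
    file.remove(written[file.exists(written)])
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Export a labeled matrix as CSV and JSON
#'
#' Writes a variation matrix or compositional mean with its behavior
#' labels, so the artifact can be re-read without positional guessing.
#'
#' @param x Named vector or labeled matrix.
#' @param path_csv,path_json Output paths (either may be `NULL` to skip).
#' @return Invisible `x`.
#' @export
export_labeled <- function(x, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) {
    df <- if (is.matrix(x)) data.frame(label = rownames(x), x,
                                       check.names = FALSE)
          else data.frame(label = names(x), value = unname(x))
    utils::write.csv(df, path_csv, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    obj <- if (is.matrix(x))
      list(labels = rownames(x), values = unname(apply(x, 1, as.list)))
    else as.list(x)
    jsonlite::write_json(obj, path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
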