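#' @name pass_scoring
#' @title PASS questionnaire scoring
#'
#' @description
#' Part one of the Procrastination Assessment Scale for Students (PASS)
#' presents six academic task areas, each followed by three 5-point
#' questions: Q1 how much the student procrastinates on the task, Q2 how
#' much of a problem that is, Q3 how much they wish to change. The total
#' procrastination score is the sum of Q1 + Q2 over the six areas (range
#' 12-60, higher = more severe); the expectation-to-change subscale is the
#' sum of Q3 (range 6-30). Severity bands: below 24 non-procrastination,
#' 24-35 mild, 36-47 moderate, 48 and above severe; moderate or severe
#' counts as chronic procrastination.
NULL

PASS_AREAS <- 6L
PASS_CATEGORIES <- c("non", "mild", "moderate", "severe")

.pass_env <- new.env(parent = emptyenv())

validate_pass_response <- function(r, areas = PASS_AREAS) {
  if (is.data.frame(r)) r <- as.matrix(r)
  if (!is.matrix(r) || nrow(r) != areas || ncol(r) != 3)
    stop("PASS response must be a ", areas, " x 3 matrix of ratings ",
         "(areas x questions)")
  bad <- which(!(r %in% 1:5) | r != round(r), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("rating out of 1..5 at area ", bad[1, 1], ", question ", bad[1, 2])
  storage.mode(r) <- "integer"
  r
}

#' Score one PASS part-one response
#'
#' @param r 6 x 3 integer matrix (or data.frame): rows = task areas, columns
#'   = Q1 (procrastination degree), Q2 (problem severity), Q3 (wish to
#'   change); every rating in 1..5.
#' @param areas Number of task areas; the score ranges scale accordingly.
#' @return A one-row data.frame: `total` (sum of Q1 + Q2), `dim_behavior`
#'   (sum Q1), `dim_severity` (sum Q2), `dim_problems`, `expectation`
#'   (sum Q3), `category`, `chronic`.
#'
#' @details The instrument gives no separate arithmetic for an "academic
#'   procrastination problems" dimension; by default `dim_problems` aliases
#'   `dim_severity` (a note is emitted once per session). Supplying
#'   per-question weights via `options(procoda.problem_weights = w)` (length
#'   3, applied to Q1..Q3 column sums) overrides the alias.
#' @examples
#' score_pass(matrix(1L, 6, 3))  # floor scores: total 12, expectation 6
#' @export
score_pass <- function(r, areas = PASS_AREAS) {
  r <- validate_pass_response(r, areas = areas)
  sums <- colSums(r)
  total <- as.integer(sums[1] + sums[2])
  w <- getOption("procoda.problem_weights", NULL)
  if (is.null(w)) {
    if (!isTRUE(.pass_env$problems_note_shown)) {
      message("score_pass: no scoring rule is defined for the 'problems' ",
              "dimension; reporting dim_problems = dim_severity")
      .pass_env$problems_note_shown <- TRUE
    }
    dim_problems <- as.integer(sums[2])
  } else {
    stopifnot(is.numeric(w), length(w) == 3)
    dim_problems <- sum(w * sums)
  }
  category <- classify_procrastination(total, areas = areas)
  data.frame(total = total,
             dim_behavior = as.integer(sums[1]),
             dim_severity = as.integer(sums[2]),
             dim_problems = dim_problems,
             expectation = as.integer(sums[3]),
             category = category,
             chronic = category %in% c("moderate", "severe"),
             stringsAsFactors = FALSE)
}

#' Severity category of a PASS total score
#'
#' Cutoffs: total < 24 "non", 24-35 "mild", 36-47 "moderate", >= 48
#' "severe". The four bands partition the attainable range exactly.
#'
#' @param total Integer vector of PASS totals (each within the attainable
#'   range, 12-60 for the six-area instrument).
#' @param areas Number of task areas (rescales the attainable range).
#' @return Character vector of categories.
#' @export
classify_procrastination <- function(total, areas = PASS_AREAS) {
  lo <- 2L * areas
  hi <- 10L * areas
  if (any(!is.finite(total)) || any(total < lo) || any(total > hi))
    stop("total out of attainable range [", lo, ", ", hi, "]")
  ifelse(total < 24, "non",
         ifelse(total <= 35, "mild",
                ifelse(total <= 47, "moderate", "severe")))
}

#' Prevalence of chronic procrastination
#'
#' Percentage of subjects in the moderate or severe bands, reported to one
#' decimal place.
#'
#' @param categories Character vector of severity categories.
#' @return Percentage in `[0, 100]`, rounded to 1 dp.
#' @examples
#' prevalence_chronic(rep(c("moderate", "non"), c(518, 468)))  # 52.5
#' @export
prevalence_chronic <- function(categories) {
  if (length(categories) == 0) stop("empty category list")
  bad <- setdiff(unique(categories), PASS_CATEGORIES)
  if (length(bad) > 0) stop("unknown category: ", bad[1])
  round(100 * mean(categories %in% c("moderate", "severe")), 1)
}

#' Score an item-level PASS response table
#'
#' @param items data.frame with columns `subject`, `area` (1-6), `q` (1-3)
#'   and `rating` (1-5), one row per answered question.
#' @param areas Number of task areas.
#' @return data.frame of [score_pass()] outputs, one row per subject, with a
#'   `subject` column.
#' @export
score_pass_items <- function(items, areas = PASS_AREAS) {
  need <- c("subject", "area", "q", "rating")
  if (!all(need %in% names(items)))
    stop("item table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(items, items$subject), function(d) {
    r <- matrix(NA_integer_, areas, 3)
    idx <- cbind(d$area, d$q)
    if (anyDuplicated(idx)) stop("duplicate item for subject ", d$subject[1])
    r[idx] <- d$rating
    if (anyNA(r)) stop("incomplete response for subject ", d$subject[1])
    cbind(subject = d$subject[1], score_pass(r, areas = areas))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
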