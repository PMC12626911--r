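#' Canonical behavior labels
#'
#' The four daily behaviors analysed by the package, in the canonical order
#' used everywhere: sleep (SLP), sedentary behavior (SB), light physical
#' activity (LPA) and moderate-to-vigorous physical activity (MVPA).
#'
#' @format Character vector of length 4.
#' @export
ap_behaviors <- c("SLP", "SB", "LPA", "MVPA")

# Default closure constant: minutes in a day.
MINUTES_PER_DAY <- 1440

#' Default reference composition (minutes/day)
#'
#' Typical daily time allocation of a college-student cohort, used as the
#' default center of the synthetic-data generator.
#'
#' @format Named numeric vector (minutes), canonical behavior order.
#' @export
ap_center_minutes <- c(SLP = 658.42, SB = 618.21, LPA = 122.86, MVPA = 40.52)

as_comp_matrix <- function(x) {
  # normalize vector/matrix/data.frame input to a numeric matrix with
  # canonical behavior columns
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!is.numeric(x)) stop("composition parts must be numeric")
  if (ncol(x) != length(ap_behaviors))
    stop("expected ", length(ap_behaviors), " behavior parts, got ", ncol(x))
  if (!is.null(colnames(x))) {
    if (!setequal(colnames(x), ap_behaviors))
      stop("behavior labels must be exactly {",
           paste(ap_behaviors, collapse = ", "), "}")
    x <- x[, ap_behaviors, drop = FALSE]
  } else {
    colnames(x) <- ap_behaviors
  }
  x
}

#' Close a vector of durations onto the simplex
#'
#' Rescales strictly positive parts proportionally so that they sum to
#' `total` (1440 for minutes of a day, 1 for proportions). Closure is the
#' basic projection of Aitchison geometry: only relative information in the
#' parts is retained.
#'
#' @param x Named numeric vector of the four behavior durations, or a matrix
#'   (one row per subject) with behavior columns.
#' @param total Positive closure constant. Default 1440 minutes.
#' @return Object of the same shape as `x`, parts summing to `total`.
#' @examples
#' close_comp(c(SLP = 658.42, SB = 618.21, LPA = 122.86, MVPA = 40.52), total = 1)
#' @export
close_comp <- function(x, total = MINUTES_PER_DAY) {
  stopifnot(is.numeric(total), length(total) == 1, total > 0)
  vec <- is.null(dim(x)) && !is.data.frame(x)
  m <- as_comp_matrix(x)
  if (nrow(m) == 0) stop("empty composition")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("all parts must be strictly positive and finite; ",
         "replace zeros first (see replace_zeros)")
  out <- m / rowSums(m) * total
  if (vec) out[1, ] else out
}

#' Replace zero durations before log-ratio analysis
#'
#' Log-ratios are undefined at zero. Self-reported 0-minute behaviors are
#' replaced by a small duration `delta` (default 1 minute, below the
#' resolution of a time-use questionnaire) and the remaining parts are
#' multiplicatively rescaled so each row still sums to its original total.
#'
#' @param x Matrix or data.frame of durations (rows = subjects) or a vector.
#' @param delta Replacement duration in the input units. Default 1.
#' @return Same shape as `x`, strictly positive. The number of replaced
#'   entries is reported via `message()` and attached as attribute
#'   `"n_replaced"`.
#' @export
replace_zeros <- function(x, delta = 1) {
  vec <- is.null(dim(x)) && !is.data.frame(x)
  m <- as_comp_matrix(x)
  if (any(!is.finite(m)) || any(m < 0))
    stop("durations must be finite and nonnegative")
  zero <- m == 0
  n_replaced <- sum(zero)
  if (n_replaced > 0) {
    if (any(rowSums(!zero) == 0)) stop("a record has all parts zero")
    tot <- rowSums(m)
    add <- rowSums(zero) * delta
    scale <- (tot - add) / tot
    if (any(scale <= 0))
      stop("delta too large: zero-replacement would drive a part nonpositive")
    m <- m * scale
    m[zero] <- delta
    message("replace_zeros: replaced ", n_replaced,
            " zero duration(s) with delta = ", delta)
  }
  out <- if (vec) m[1, ] else m
  attr(out, "n_replaced") <- n_replaced
  out
}

#' Compositional (geometric) mean
#'
#' Closed vector of part-wise geometric means - the center of a compositional
#' sample in Aitchison geometry.
#'
#' @param x Matrix/data.frame of strictly positive compositions, one row per
#'   subject.
#' @param total Closure constant of the result.
#' @return Named composition summing to `total`.
#' @export
comp_mean <- function(x, total = MINUTES_PER_DAY) {
  m <- as_comp_matrix(x)
  if (nrow(m) < 1) stop("need at least one sample")
  if (any(m <= 0)) stop("all parts must be strictly positive")
  close_comp(exp(colMeans(log(m))), total = total)
}

#' Variation matrix of pairwise log-ratios
#'
#' Entry (i, j) is the sample variance (n - 1 denominator) over subjects of
#' `log(x_i / x_j)`. Small entries flag pairs of behaviors that move
#' proportionally; the matrix is symmetric with a zero diagonal and is
#' invariant to rescaling every sample by a positive constant.
#'
#' @param x Matrix/data.frame of strictly positive compositions (>= 2 rows).
#' @return Symmetric D x D matrix with behavior dimnames.
#' @export
variation_matrix <- function(x) {
  m <- as_comp_matrix(x)
  if (nrow(m) < 2) stop("need at least two samples for a variation matrix")
  if (any(m <= 0)) stop("all parts must be strictly positive")
  lm_ <- log(m)
  d <- ncol(m)
  out <- matrix(0, d, d, dimnames = list(ap_behaviors, ap_behaviors))
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      v <- stats::var(lm_[, i] - lm_[, j])
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Most co-dependent behavior pair
#'
#' Finds the smallest off-diagonal entry of a variation matrix: the pair of
#' behaviors whose log-ratio varies least across subjects, i.e. the pair most
#' likely to trade time proportionally. Ties are broken by canonical label
#' order.
#'
#' @param vm Symmetric variation matrix with behavior dimnames.
#' @param rank Which order statistic to return (1 = lowest, 2 = second
#'   lowest, ...).
#' @return List with `pair` (two labels, canonical order) and `value`.
#' @export
strongest_codependence <- function(vm, rank = 1) {
  stopifnot(is.matrix(vm), nrow(vm) == ncol(vm), nrow(vm) >= 2)
  labs <- rownames(vm)
  if (is.null(labs)) labs <- colnames(vm)
  if (is.null(labs)) stop("variation matrix must carry behavior labels")
  pairs <- which(upper.tri(vm), arr.ind = TRUE)
  # enumerate in canonical order (row-major over i < j)
  ord <- order(pairs[, "row"], pairs[, "col"])
  pairs <- pairs[ord, , drop = FALSE]
  vals <- vm[pairs]
  if (rank < 1 || rank > length(vals)) stop("rank out of range")
  sel <- order(vals)[rank]  # stable: ties keep canonical enumeration order
  list(pair = c(labs[pairs[sel, "row"]], labs[pairs[sel, "col"]]),
       value = unname(vals[sel]))
}

#' Pivot (sequential binary partition) ilr basis
#'
#' Builds the orthonormal contrast matrix of pivot coordinates for a given
#' ordering of the behaviors. The first coordinate contrasts the leading
#' behavior against the geometric mean of the others, which makes its
#' regression coefficient directly interpretable as "relative dominance of
#' that behavior within the day".
#'
#' @param order Permutation of [ap_behaviors]; the first element leads.
#' @return Object of class `pivot_basis`: list with `contrast`
#'   ((D-1) x D matrix, columns in canonical behavior order) and `order`.
#' @export
pivot_basis <- function(order = ap_behaviors) {
  if (!identical(sort(order), sort(ap_behaviors)))
    stop("order must be a permutation of {",
         paste(ap_behaviors, collapse = ", "), "}")
  d <- length(order)
  V <- matrix(0, d - 1, d, dimnames = list(paste0("ilr", seq_len(d - 1)), order))
  for (i in seq_len(d - 1)) {
    r <- d - i
    V[i, i] <- sqrt(r / (r + 1))
    V[i, (i + 1):d] <- -1 / sqrt(r * (r + 1))
  }
  V <- V[, ap_behaviors, drop = FALSE]  # canonical column order
  structure(list(contrast = V, order = order), class = "pivot_basis")
}

#' @export
print.pivot_basis <- function(x, ...) {
  cat("pivot ilr basis, leading behavior:", x$order[1], "\n")
  print(round(x$contrast, 4))
  invisible(x)
}

#' Isometric log-ratio (pivot) coordinates
#'
#' Maps compositions to D-1 unconstrained real coordinates via
#' `contrast %*% log(parts)`. Coordinates do not depend on the closure
#' constant, so minutes and proportions give identical results.
#'
#' @param x Strictly positive composition vector or matrix (rows = subjects).
#' @param basis A [pivot_basis()]; default canonical order.
#' @return Numeric vector of length D-1, or an n x (D-1) matrix.
#' @export
ilr_coords <- function(x, basis = pivot_basis()) {
  stopifnot(inherits(basis, "pivot_basis"))
  vec <- is.null(dim(x)) && !is.data.frame(x)
  m <- as_comp_matrix(x)
  if (any(m <= 0)) stop("zero or negative part: replace zeros upstream")
  z <- log(m) %*% t(basis$contrast)
  if (vec) z[1, ] else z
}

#' Inverse ilr transform
#'
#' @param z Numeric vector of length D-1, or matrix with D-1 columns.
#' @param basis A [pivot_basis()].
#' @param total Closure constant of the reconstructed composition.
#' @return Composition (vector or matrix) in canonical behavior order.
#' @export
ilr_inverse <- function(z, basis = pivot_basis(), total = MINUTES_PER_DAY) {
  stopifnot(inherits(basis, "pivot_basis"))
  vec <- is.null(dim(z))
  zm <- if (vec) matrix(z, nrow = 1) else as.matrix(z)
  if (ncol(zm) != nrow(basis$contrast))
    stop("expected ", nrow(basis$contrast), " ilr coordinates, got ", ncol(zm))
  x <- exp(zm %*% basis$contrast)
  colnames(x) <- colnames(basis$contrast)
  out <- close_comp(x, total = total)
  if (vec) out[1, ] else out
}
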