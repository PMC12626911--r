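test_that("closure rescales proportionally, idempotently, and rejects bad input", {
  raw <- c(SLP = 658.42, SB = 618.21, LPA = 122.86, MVPA = 40.52)
  p <- close_comp(raw, total = 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p / p["MVPA"]), unname(raw / raw["MVPA"]),
               tolerance = 1e-12)
  # published rounded shares of the day
  expect_equal(unname(round(p, 2)),
               c(0.46, 0.43, 0.09, 0.03))
  # symmetry and idempotence
  expect_equal(unname(close_comp(c(1, 1, 1, 1), total = 1)), rep(0.25, 4))
  expect_equal(close_comp(close_comp(raw, 1440), 1440),
               close_comp(raw, 1440), tolerance = 1e-12)
  expect_error(close_comp(c(1, -1, 2, 3)), "positive")
  expect_error(close_comp(c(SLP = 1, SB = 1, LPA = 1, X = 1)), "labels")
})

test_that("zero replacement preserves the row total and rescales the rest", {
  x <- c(SLP = 700, SB = 700, LPA = 40, MVPA = 0)
  expect_message(y <- replace_zeros(x, delta = 1), "replaced 1")
  expect_equal(sum(y), sum(x), tolerance = 1e-9)
  expect_equal(unname(y["MVPA"]), 1)
  expect_gt(min(y), 0)
  # untouched when already positive
  expect_equal(as.numeric(replace_zeros(c(1, 2, 3, 4))), c(1, 2, 3, 4))
})

test_that("compositional mean is the closed geometric mean", {
  m <- close_comp(rbind(c(1, 2, 4, 8), c(4, 2, 1, 8)))
  colnames(m) <- ap_behaviors
  # part-wise geometric means of the two rows are (2, 2, 2, 8)
  expect_equal(unname(comp_mean(m, total = 1)),
               c(2, 2, 2, 8) / 14, tolerance = 1e-12)
  one <- close_comp(c(SLP = 600, SB = 600, LPA = 150, MVPA = 90))
  expect_equal(comp_mean(rbind(one, one, one)), one, tolerance = 1e-12)
  expect_error(comp_mean(matrix(numeric(0), ncol = 4)), "at least one")
})

test_that("variation matrix: hand case, symmetry, scale invariance, oracle", {
  # two samples differing only in the first part by a factor e:
  # var over {0, 1} with the n-1 convention is 0.5
  m <- rbind(c(exp(1), 1, 1, 1), c(1, 1, 1, 1))
  colnames(m) <- ap_behaviors
  vm <- variation_matrix(m)
  expect_equal(vm["SLP", "SB"], 0.5, tolerance = 1e-12)
  expect_equal(vm["LPA", "MVPA"], 0, tolerance = 1e-12)
  expect_true(all(diag(vm) == 0))

  x <- random_comp_matrix(20, seed = 11)
  vm1 <- variation_matrix(x)
  expect_equal(vm1, t(vm1))
  expect_equal(variation_matrix(x * 3.7), vm1, tolerance = 1e-12)
  expect_equal(variation_matrix(close_comp(x, total = 1)), vm1,
               tolerance = 1e-12)
  # identical samples -> all zero
  expect_equal(max(abs(variation_matrix(x[c(1, 1, 1), ]))), 0)
  # independent oracle via the log covariance matrix:
  # var(log xi - log xj) = Cii + Cjj - 2 Cij
  C <- stats::cov(log(x))
  oracle <- outer(diag(C), diag(C), "+") - 2 * C
  dimnames(oracle) <- dimnames(vm1)
  expect_equal(vm1, oracle, tolerance = 1e-10)
  expect_error(variation_matrix(x[1, , drop = FALSE]), "two samples")
})

test_that("strongest codependence finds the printed minima and breaks ties canonically", {
  vm <- printed_variation_matrix()
  low <- strongest_codependence(vm)
  expect_setequal(low$pair, c("MVPA", "LPA"))
  expect_equal(low$value, 0.05)
  second <- strongest_codependence(vm, rank = 2)
  expect_setequal(second$pair, c("SLP", "SB"))
  expect_equal(second$value, 0.07)
  # all-equal off-diagonals -> first canonical pair
  flat <- matrix(0.3, 4, 4, dimnames = list(ap_behaviors, ap_behaviors))
  diag(flat) <- 0
  expect_equal(strongest_codependence(flat)$pair, c("SLP", "SB"))
})

test_that("pivot basis is orthonormal with the closed-form leading row", {
  for (lead in ap_behaviors) {
    b <- pivot_basis(c(lead, setdiff(ap_behaviors, lead)))
    V <- b$contrast
    expect_equal(V %*% t(V), diag(3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(unname(rowSums(V)), rep(0, 3), tolerance = 1e-12)  # orthogonal to 1
    expect_equal(unname(V[1, lead]), sqrt(3 / 4), tolerance = 1e-12)
    expect_equal(unname(V[1, setdiff(ap_behaviors, lead)]),
                 rep(-sqrt(1 / 12), 3), tolerance = 1e-12)
  }
  expect_error(pivot_basis(c("SLP", "SLP", "LPA", "MVPA")), "permutation")
})

test_that("ilr coordinates: zero at the barycenter, scale invariant, exact roundtrip", {
  expect_equal(ilr_coords(c(SLP = 360, SB = 360, LPA = 360, MVPA = 360)),
               c(ilr1 = 0, ilr2 = 0, ilr3 = 0), tolerance = 1e-12)
  x <- c(SLP = 658.42, SB = 618.21, LPA = 122.86, MVPA = 40.52)
  expect_equal(ilr_coords(x), ilr_coords(close_comp(x, total = 1)),
               tolerance = 1e-12)
  # roundtrips
  expect_equal(ilr_inverse(ilr_coords(x), total = sum(x)), close_comp(x, sum(x)),
               tolerance = 1e-12)
  m <- random_comp_matrix(100, seed = 3)
  back <- ilr_inverse(ilr_coords(m))
  expect_lt(max(abs(back - m)), 1e-9)
  z <- matrix(rnorm(300), ncol = 3)
  expect_lt(max(abs(ilr_coords(ilr_inverse(z)) - z)), 1e-9)
  expect_equal(unname(ilr_inverse(c(0, 0, 0), total = 1)), rep(0.25, 4))
  expect_error(ilr_coords(c(SLP = 0, SB = 1, LPA = 1, MVPA = 1)), "zero")
  expect_error(ilr_inverse(c(1, 2)), "coordinates")
})

test_that("coordinates under different pivot orders are an isometry apart", {
  m <- random_comp_matrix(25, seed = 5)
  z1 <- ilr_coords(m, pivot_basis(ap_behaviors))
  z2 <- ilr_coords(m, pivot_basis(c("MVPA", "SB", "SLP", "LPA")))
  expect_equal(sqrt(rowSums(z1^2)), sqrt(rowSums(z2^2)), tolerance = 1e-9)
})
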