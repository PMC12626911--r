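# Shared fixtures, all built in code.

# Pairwise log-ratio variances as published for the reference cohort
# (canonical order SLP, SB, LPA, MVPA).
printed_variation_matrix <- function() {
  vm <- matrix(0, 4, 4, dimnames = list(ap_behaviors, ap_behaviors))
  vals <- c(SLP.SB = 0.07, SLP.LPA = 0.10, SLP.MVPA = 0.15,
            SB.LPA = 0.08, SB.MVPA = 0.12, LPA.MVPA = 0.05)
  pairs <- strsplit(names(vals), ".", fixed = TRUE)
  for (k in seq_along(vals)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    vm[i, j] <- vals[[k]]; vm[j, i] <- vals[[k]]
  }
  vm
}

# random strictly positive compositions (minutes)
random_comp_matrix <- function(n, seed = 42) {
  set.seed(seed)
  m <- matrix(exp(stats::rnorm(n * 4, log(c(650, 600, 120, 40)), 0.3)),
              ncol = 4, byrow = TRUE, dimnames = list(NULL, ap_behaviors))
  close_comp(m)
}

# cohort whose outcome is an exact linear function of the design
# (no residual noise): OLS must interpolate it
noiseless_cohort <- function(n = 120, seed = 7,
                             beta_ilr = c(1.5, -2, 0.8),
                             beta_cov = c(gender = 2, age = -0.5,
                                          residence = 1),
                             intercept = 5) {
  cfg <- generator_config(n = n, seed = seed, noise_sd = 1)
  data <- generate_cohort(cfg)$data
  m <- as.matrix(data[, c("slp_min", "sb_min", "lpa_min", "mvpa_min")])
  colnames(m) <- ap_behaviors
  Z <- ilr_coords(close_comp(m))
  data$ap_total <- intercept + drop(Z %*% beta_ilr) +
    beta_cov[["gender"]] * data$gender + beta_cov[["age"]] * data$age +
    beta_cov[["residence"]] * data$residence
  list(data = data, beta_ilr = beta_ilr, beta_cov = beta_cov,
       intercept = intercept)
}
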