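# Shared fixtures, built in code at test time.

# A noiseless site table responding linearly to a single gamma = 1 trait.
linear_trait <- function(q_sd = 0) {
  trait_spec(gamma_mean = 1, gamma_sd = 0, q_sd = q_sd, trait_id = "lin")
}

# Noiseless methylation matrix m = m0 + rate * age for given per-site params.
affine_matrix <- function(ages, m0, rates) {
  m <- m0 + rates %o% ages
  dimnames(m) <- list(sprintf("cg%04d", seq_along(m0)),
                      sprintf("s%04d", seq_along(ages)))
  m
}

# A site whose Pearson correlation with `ages` is exactly `rho`:
# mixes the standardized age vector with an orthogonal unit vector.
site_with_pcc <- function(ages, rho, amplitude = 0.1, center = 0.5, seed = 1) {
  x <- scale(ages)[, 1]
  z <- withr::with_seed(seed, stats::rnorm(length(ages)))
  z <- stats::residuals(stats::lm(z ~ x))
  z <- z / sqrt(sum(z^2) / (length(z) - 1))
  center + amplitude * (rho * x + sqrt(1 - rho^2) * z)
}

# One simulated study replicate at the benchmark design.
sim_replicate <- function(binary_q = 0.995, health_sd = 0.005, n = 500,
                          seed = 1) {
  design <- benchmark_design(binary_q = binary_q, health_sd = health_sd,
                          seed = substream_seed(seed, "design"))
  cohort <- simulate_cohort(n, c(0, 100), health_sd = health_sd,
                            traits = design$traits,
                            seed = substream_seed(seed, "cohort"))
  matrix <- simulate_methylation(cohort, design$sites,
                                 seed = substream_seed(seed, "meth"))
  list(design = design, cohort = cohort, matrix = matrix)
}

# The 3-blob point cloud used to cross-check affinity propagation against an
# independent reference implementation (labels frozen in the test).
ap_blobs <- function() {
  centers <- matrix(c(0, 0, 0, 0, 0,
                      2, 2, 0, 0, 0,
                      0, 0, 3, 3, 0), 3, 5, byrow = TRUE)
  withr::with_seed(42, do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(stats::rnorm(8 * 5, 0, 0.15), 8, 5), 2, centers[k, ], "+")
  })))
}
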