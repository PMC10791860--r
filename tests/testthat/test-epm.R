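test_that("per-site models recover exact noiseless parameters", {
  ages <- seq(5, 90, length.out = 40)
  m <- affine_matrix(ages, m0 = c(0.2, 0.85), rates = c(0.003, -0.004))
  fit <- fit_site_models(m, ages)
  expect_equal(fit$m0, c(0.2, 0.85), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fit$rates, c(0.003, -0.004), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a noise-only site has a slope near zero", {
  n <- 1000
  ages <- withr::with_seed(1, stats::runif(n, 0, 100))
  noise <- withr::with_seed(2, stats::rnorm(n, 0, 0.05))
  m <- rbind(0.5 + noise, 0.4 + 0.001 * ages)
  fit <- fit_site_models(m, ages)
  se_slope <- 0.05 / sqrt(sum((ages - mean(ages))^2))
  expect_lt(abs(fit$rates[1]), 3 * se_slope)
})

test_that("two samples with distinct states are fit exactly", {
  m <- matrix(c(0.2, 0.5, 0.7, 0.1), 2, 2)
  fit <- fit_site_models(m, c(10, 60))
  resid <- m - (fit$m0 + fit$rates %o% c(10, 60))
  expect_lt(max(abs(resid)), 1e-14)
})

test_that("constant states and all-zero rates are rejected", {
  m <- matrix(runif(6), 2, 3)
  expect_error(fit_site_models(m, c(5, 5, 5)), "constant")
  expect_error(update_states(m, c(0.1, 0.2), c(0, 0)), "zero")
})

test_that("the state update is the exact per-sample least-squares minimizer", {
  # single site: algebraic inversion
  m0 <- 0.2
  r <- 0.004
  s_true <- c(3, 47, 80)
  m <- matrix(m0 + r * s_true, 1, 3)
  expect_equal(update_states(m, m0, r), s_true, tolerance = 1e-12)

  # 5-site toy vs brute-force 1-D minimization of the per-sample SSE
  m0 <- c(0.1, 0.3, 0.6, 0.8, 0.45)
  r <- c(0.004, -0.002, 0.001, -0.003, 0.0025)
  m <- withr::with_seed(3, matrix(runif(5 * 4, 0.05, 0.95), 5, 4))
  states <- update_states(m, m0, r)
  for (j in 1:4) {
    sse_j <- function(s) sum((m[, j] - m0 - r * s)^2)
    # coarse bracketing grid, then the exact vertex of the quadratic through
    # the three lowest points (the SSE is quadratic in s)
    grid <- seq(-500, 500, by = 1)
    i0 <- which.min(vapply(grid, sse_j, numeric(1)))
    x <- grid[i0 + (-1:1)]
    f <- vapply(x, sse_j, numeric(1))
    vertex <- x[2] - 0.5 *
      ((x[2] - x[1])^2 * (f[2] - f[3]) - (x[2] - x[3])^2 * (f[2] - f[1])) /
      ((x[2] - x[1]) * (f[2] - f[3]) - (x[2] - x[3]) * (f[2] - f[1]))
    expect_equal(states[j], vertex, tolerance = 1e-8)
  }
})

test_that("the state update never increases the total squared error", {
  withr::with_seed(4, {
    for (k in 1:5) {
      m <- matrix(runif(30 * 20), 30, 20)
      states0 <- runif(20, 0, 100)
      fit <- fit_site_models(m, states0)
      sse0 <- sum((m - (fit$m0 + fit$rates %o% states0))^2)
      states1 <- update_states(m, fit$m0, fit$rates)
      sse1 <- sum((m - (fit$m0 + fit$rates %o% states1))^2)
      expect_lte(sse1, sse0)
    }
  })
})

test_that("noiseless linear data is a fixed point reached in <= 2 iterations", {
  ages <- seq(1, 99, length.out = 50)
  m <- affine_matrix(ages, m0 = seq(0.1, 0.4, length.out = 8),
                     rates = seq(-0.004, 0.004, length.out = 8))
  fit <- fit_epm(m, ages)
  expect_lte(fit$n_iter, 2)
  expect_equal(fit$states, ages, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the EM error trace is non-increasing on noisy input", {
  for (seed in 1:3) {
    rep <- sim_replicate(n = 120, seed = seed)
    fit <- fit_epm(rep$matrix, rep$cohort$age, tol = 1e-10, max_iter = 30)
    expect_true(all(diff(fit$error_trace) <= 1e-9))
  }
})

test_that("nonlinear traits give states that track the trait, not the age", {
  # sqrt-age trait, no noise: states monotone in age, sites better explained
  # by states than by age
  tr <- trait_spec(gamma_mean = 0.5, trait_id = "sq")
  co <- simulate_cohort(100, c(1, 100), traits = tr, seed = 5)
  sites <- purrr::map_dfr(1:6, function(i) {
    site_spec(paste0("cg", i), m0 = 0.1 + 0.05 * i,
              rate = 0.02 + 0.002 * i, noise_sd = 0, weights = c(sq = 1))
  })
  m <- simulate_methylation(co, sites, seed = 1)
  fit <- fit_epm(m, co$age)
  ord <- order(co$age)
  expect_true(all(diff(fit$states[ord]) > 0))
  sse_states <- sum((m - (fit$m0 + fit$rates %o% fit$states))^2)
  site_age <- fit_site_models(m, co$age)
  sse_age <- sum((m - (site_age$m0 + site_age$rates %o% co$age))^2)
  expect_lt(sse_states, sse_age)
})

test_that("planted parameters are recovered up to the affine state anchor", {
  withr::with_seed(6, {
    s_true <- sort(runif(60, 0, 100))
    m0_true <- runif(15, 0.2, 0.6)
    r_true <- runif(15, -0.003, 0.003)
    ages <- s_true * 0.8 + 4  # the anchor differs from the generative states
    m <- m0_true + r_true %o% s_true
    rownames(m) <- sprintf("cg%02d", 1:15)
    fit <- fit_epm(m, ages, tol = 1e-12, max_iter = 200)
    anchor <- stats::lm(fit$states ~ s_true)
    b <- stats::coef(anchor)[[2]]
    a <- stats::coef(anchor)[[1]]
    expect_equal(fit$rates * b, r_true, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(fit$m0 + fit$rates * a, m0_true, tolerance = 1e-6,
                 ignore_attr = TRUE)
  })
})

test_that("doubling the age initialization doubles states and halves rates", {
  rep <- sim_replicate(n = 80, seed = 7)
  f1 <- fit_epm(rep$matrix, rep$cohort$age, tol = 1e-10)
  f2 <- fit_epm(rep$matrix, rep$cohort$age * 2, tol = 1e-10)
  expect_equal(f2$states, f1$states * 2, tolerance = 1e-6)
  expect_equal(f2$rates, f1$rates / 2, tolerance = 1e-6)
})

test_that("site order does not affect the fitted states", {
  rep <- sim_replicate(n = 60, seed = 8)
  perm <- withr::with_seed(1, sample(nrow(rep$matrix)))
  f1 <- fit_epm(rep$matrix, rep$cohort$age)
  f2 <- fit_epm(rep$matrix[perm, ], rep$cohort$age)
  expect_equal(f1$states, f2$states, tolerance = 1e-12)
})

test_that("prediction reproduces training states and inverts exact profiles", {
  rep <- sim_replicate(n = 80, seed = 9)
  fit <- fit_epm(rep$matrix, rep$cohort$age)
  expect_equal(predict_states(fit, rep$matrix), fit$states, tolerance = 1e-10)
  # an exact profile maps back to its state
  s_star <- 42.5
  prof <- matrix(fit$m0 + fit$rates * s_star,
                 dimnames = list(fit$site_ids, "new"))
  expect_equal(predict_states(fit, prof), s_star, tolerance = 1e-10,
               ignore_attr = TRUE)
  # duplicated samples get identical states
  two <- cbind(prof, prof)
  colnames(two) <- c("a", "b")
  s2 <- predict_states(fit, two)
  expect_equal(s2[1], s2[2])
  # missing sites are reported by name
  expect_error(predict_states(fit, rep$matrix[-1, ]), fit$site_ids[1])
})

test_that("model errors match a naive double-loop computation", {
  withr::with_seed(10, {
    m <- matrix(runif(100), 10, 10)
    mod <- list(m0 = runif(10), rates = runif(10, -0.01, 0.01),
                states = runif(10, 0, 100))
    got <- model_error(m, mod)
    sse <- 0
    abs_sum <- 0
    for (i in 1:10) {
      for (j in 1:10) {
        r <- m[i, j] - mod$m0[i] - mod$rates[i] * mod$states[j]
        sse <- sse + r^2
        abs_sum <- abs_sum + abs(r)
      }
    }
    expect_equal(got$sse, sse, tolerance = 1e-12)
    expect_equal(got$mae, abs_sum / 100, tolerance = 1e-12)
  })
  # a perfect model has zero error
  ages <- 1:10
  m <- affine_matrix(ages, c(0.2, 0.4), c(0.01, -0.01))
  fit <- fit_epm(m, ages)
  err <- model_error(m, fit)
  expect_equal(err$sse, 0, tolerance = 1e-16)
  expect_equal(err$mae, 0, tolerance = 1e-16)
})

test_that("the state-to-age map inverts the square-root age trend", {
  ages <- seq(1, 95, length.out = 80)
  states <- 2 + 0.5 * ages + 4 * sqrt(ages)
  map <- fit_state_age_map(states, ages)
  expect_equal(predict(map, states), ages, tolerance = 1e-3)
})

test_that("epm fits expose tidy, glance and degenerate-input errors", {
  rep <- sim_replicate(n = 50, seed = 13)
  fit <- fit_epm(rep$matrix, rep$cohort$age)
  td <- tidy(fit)
  expect_named(td, c("site_id", "m0", "rate"))
  expect_equal(nrow(td), nrow(rep$matrix))
  ts <- tidy(fit, "samples")
  expect_equal(nrow(ts), 50)
  g <- glance(fit)
  expect_true(g$converged)
  expect_error(fit_epm(rep$matrix * NA, rep$cohort$age), "non-finite")
  expect_error(fit_epm(rep$matrix[1, , drop = FALSE], rep$cohort$age),
               "2 sites")
})
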