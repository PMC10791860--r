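#' Simulate a cohort of samples with realized phenotypes
#'
#' Samples are assigned an age from a uniform distribution over `age_range`
#' and a latent health value \eqn{h_j \sim N(0, \mathrm{health\_sd}^2)}. Each
#' trait in `traits` is then realized for every sample as
#' \eqn{p_{k,j} = \mathrm{Age}_j^{\gamma_k} q_{k,j}} (one \eqn{\gamma_k} draw
#' per trait, one exposure draw per sample per trait; health-coupled traits
#' have their exposure mean shifted by \eqn{h_j}).
#'
#' @param n_samples Number of samples (>= 1).
#' @param age_range Length-2 numeric `(lo, hi)`, `lo < hi`, ages in years.
#' @param health_sd Standard deviation of the per-sample health value.
#' @param traits Tibble of traits (rows from [trait_spec()]); must be
#'   non-empty. Missing `trait_id`s are filled as `t01`, `t02`, ...
#' @param seed Integer seed; the cohort is bit-identical across runs for a
#'   fixed seed, and each trait draws from its own sub-stream.
#' @return A tibble with one row per sample: `sample_id`, `age`, `health`,
#'   one `p_<trait_id>` column per trait and one `on_<trait_id>` 0/1 column
#'   per binary trait. The realized trait table (with a `gamma` column) is
#'   attached as attribute `"traits"`.
#' @export
#' @examples
#' tr <- trait_spec(gamma_mean = 1)
#' simulate_cohort(5, c(0, 100), health_sd = 0, traits = tr, seed = 1)
simulate_cohort <- function(n_samples, age_range = c(0, 100), health_sd = 0,
                            traits, seed = 1) {
  stopifnot(n_samples >= 1, length(age_range) == 2)
  if (age_range[1] >= age_range[2]) stop("age_range must satisfy lo < hi", call. = FALSE)
  if (age_range[1] < 0) stop("ages must be non-negative", call. = FALSE)
  if (missing(traits) || is.null(traits) || nrow(traits) == 0) {
    stop("`traits` must contain at least one trait", call. = FALSE)
  }
  traits <- fill_trait_ids(traits)

  ages <- with_substream(substream_seed(seed, "ages"),
                         stats::runif(n_samples, age_range[1], age_range[2]))
  health <- if (health_sd == 0) {
    rep(0, n_samples)
  } else {
    with_substream(substream_seed(seed, "health"),
                   stats::rnorm(n_samples, 0, health_sd))
  }

  out <- tibble::tibble(
    sample_id = sprintf("s%04d", seq_len(n_samples)),
    age = ages,
    health = health
  )

  gammas <- numeric(nrow(traits))
  for (i in seq_len(nrow(traits))) {
    tr <- traits[i, ]
    tseed <- substream_seed(seed, "trait", i)
    gamma <- draw_gamma(tr, substream_seed(tseed, "gamma"))
    gammas[i] <- gamma
    ex <- draw_exposure(tr, health, substream_seed(tseed, "q"))
    p <- if (gamma == 0) ex$q else ages^gamma * ex$q
    out[[paste0("p_", tr$trait_id)]] <- p
    if (tr$binary) out[[paste0("on_", tr$trait_id)]] <- as.integer(ex$on)
  }
  traits$gamma <- gammas
  attr(out, "traits") <- traits
  out
}

# Exposure draw retaining the binary on/off indicator.
draw_exposure <- function(trait, health, seed) {
  n <- length(health)
  with_substream(seed, {
    if (trait$binary) {
      on <- stats::runif(n) < trait$binary_prob
      list(q = ifelse(on, trait$binary_q, 1), on = on)
    } else {
      mu <- trait$q_mean + if (trait$health_coupled) health else 0
      list(q = stats::rnorm(n, mu, trait$q_sd), on = rep(NA, n))
    }
  })
}

fill_trait_ids <- function(traits) {
  if (!"trait_id" %in% names(traits)) traits$trait_id <- NA_character_
  missing <- is.na(traits$trait_id)
  traits$trait_id[missing] <- sprintf("t%02d", which(missing))
  if (anyDuplicated(traits$trait_id)) stop("duplicate trait_id", call. = FALSE)
  traits
}

#' Describe one simulated methylation site
#'
#' A site responds to a weighted sum of trait phenotypes:
#' \eqn{\hat m_{ij} = \mathrm{clamp}(m^0_i + r_i \sum_k w_{ik} p_{k,j} +
#' \epsilon_{ij},\ 0,\ m^{max}_i)} with \eqn{\epsilon_{ij} \sim
#' N(0, \mathrm{noise\_sd}_i^2)}. Weights are non-negative; the direction of
#' methylation change with aging is carried by the sign of `rate`.
#'
#' @param site_id Identifier.
#' @param m0 Initial (state-zero) beta value, in `[0, m_max]`.
#' @param rate Change in beta per unit of the site's weighted phenotype sum.
#' @param noise_sd Measurement noise standard deviation (beta units).
#' @param weights Named numeric vector of non-negative trait weights
#'   (names are `trait_id`s).
#' @param m_max Maximum observable beta value (ceiling applied after noise).
#' @return A one-row tibble; bind rows to build a site table.
#' @export
site_spec <- function(site_id, m0, rate, noise_sd, weights, m_max = 1) {
  if (m0 < 0 || m_max > 1 || m0 > m_max) {
    stop("need 0 <= m0 <= m_max <= 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(weights < 0)) stop("trait weights must be non-negative", call. = FALSE)
  tibble::tibble(
    site_id = site_id, m0 = as.double(m0), m_max = as.double(m_max),
    rate = as.double(rate), noise_sd = as.double(noise_sd),
    weights = list(weights)
  )
}

# Expected span of a site's weighted phenotype sum over an age range, at the
# traits' mean exponents and neutral exposure. Used to scale site rates.
expected_state_span <- function(weights, traits, age_range) {
  idx <- match(names(weights), traits$trait_id)
  if (anyNA(idx)) {
    stop("site references unknown trait(s): ",
         paste(names(weights)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  spans <- vapply(seq_along(idx), function(k) {
    tr <- traits[idx[k], ]
    if (tr$gamma_mean == 0) return(0)
    (age_range[2]^tr$gamma_mean - age_range[1]^tr$gamma_mean) * tr$q_mean
  }, numeric(1))
  sum(weights * spans)
}

# Draw random site parameters for a list of weight vectors, following the
# package's site model: hyper/hypermethylating direction with probability 1/2,
# m0 ~ U(0.05, 0.35) (hyper) or U(0.65, 0.95) (hypo), |rate| scaled so the
# expected beta range across the age span is U(0.1, 0.5), noise_sd
# ~ U(0.003, 0.01), m_max = 1.
random_sites <- function(weight_list, traits, age_range = c(0, 100), seed = 1,
                         id_prefix = "cg") {
  n <- length(weight_list)
  purrr::map_dfr(seq_len(n), function(i) {
    w <- weight_list[[i]]
    span <- expected_state_span(w, traits, age_range)
    if (span <= 0) span <- 1
    with_substream(substream_seed(seed, "site", i), {
      hyper <- stats::runif(1) < 0.5
      m0 <- if (hyper) stats::runif(1, 0.05, 0.35) else stats::runif(1, 0.65, 0.95)
      target_range <- stats::runif(1, 0.1, 0.5)
      rate <- (if (hyper) 1 else -1) * target_range / span
      noise_sd <- stats::runif(1, 0.003, 0.01)
      site_spec(sprintf("%s%04d", id_prefix, i), m0, rate, noise_sd, w)
    })
  })
}

#' Simulate a beta-value methylation matrix for a cohort
#'
#' For each site and sample,
#' \eqn{\hat m_{ij} = \mathrm{clamp}(m^0_i + r_i \sum_k w_{ik} p_{k,j} +
#' \epsilon_{ij},\ 0,\ m^{max}_i)}. All emitted values are in `[0, 1]` and no
#' entries are missing; the number of clamped entries is attached as attribute
#' `"n_clamped"`.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param sites Site table (rows from [site_spec()] or a design such as
#'   [benchmark_design()]).
#' @param seed Integer seed; per-site noise uses independent sub-streams.
#' @param clamp If `FALSE`, the raw (unclamped) values are returned; intended
#'   for calibration checks only.
#' @return Numeric matrix, sites in rows (rownames `site_id`), samples in
#'   columns (colnames `sample_id`, in cohort order).
#' @export
simulate_methylation <- function(cohort, sites, seed = 1, clamp = TRUE) {
  trait_ids <- sub("^p_", "", grep("^p_", names(cohort), value = TRUE))
  n_samp <- nrow(cohort)
  n_site <- nrow(sites)
  P <- t(as.matrix(cohort[, paste0("p_", trait_ids), drop = FALSE]))
  rownames(P) <- trait_ids

  W <- matrix(0, n_site, length(trait_ids), dimnames = list(sites$site_id, trait_ids))
  for (i in seq_len(n_site)) {
    w <- sites$weights[[i]]
    unknown <- setdiff(names(w), trait_ids)
    if (length(unknown)) {
      stop("site ", sites$site_id[i], " references unknown trait(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    W[i, names(w)] <- w
  }

  signal <- sites$m0 + sites$rate * (W %*% P)
  noise <- matrix(0, n_site, n_samp)
  for (i in seq_len(n_site)) {
    if (sites$noise_sd[i] > 0) {
      noise[i, ] <- with_substream(substream_seed(seed, "site-noise", i),
                                   stats::rnorm(n_samp, 0, sites$noise_sd[i]))
    }
  }
  m <- signal + noise
  dimnames(m) <- list(sites$site_id, cohort$sample_id)
  if (!clamp) return(m)
  lo <- pmax(m, 0)
  hi <- pmin(lo, sites$m_max)  # recycles m_max down columns (sites in rows)
  n_clamped <- sum(m < 0 | m > sites$m_max)
  out <- hi
  attr(out, "n_clamped") <- n_clamped
  out
}

#' The benchmark simulation design: traits and sites
#'
#' Builds the study design used throughout the package's simulation
#' benchmarks: 60 continuous traits (10 health-coupled and 20 age-only with
#' \eqn{\gamma \sim N(0.5, 0.01^2)}; 10 health-coupled and 20 age-only with
#' \eqn{\gamma \sim N(1, 0.01^2)}; exposure sd 0.05 each) plus one sex-like
#' binary trait (\eqn{\gamma = 0.5}, on-probability 0.5, on-exposure
#' `binary_q`). Five methylation sites are generated per continuous trait, 50
#' sites for the binary trait, and 50 mixture sites each equally weighted
#' (1/5) over four randomly chosen continuous traits plus the binary trait —
#' 400 sites in total by default; `n_total_sites` can pad the design with
#' further single-trait continuous sites (cycling over the continuous traits)
#' e.g. to 450.
#'
#' @param binary_q On-exposure of the binary trait, in `[0.995, 1]`
#'   (1 = no effect).
#' @param health_sd Standard deviation of the latent health value that shifts
#'   the exposure mean of health-coupled traits (the cohort draws it; stored
#'   in the returned design for bookkeeping).
#' @param seed Integer seed for site-parameter draws and mixture assignment.
#' @param n_total_sites Total site count; the default `400` is the enumerated
#'   design, `450` pads with 50 extra single-trait sites.
#' @param age_range Age range used to scale site rates.
#' @param sample_effect_sd Intrinsic per-sample exposure standard deviation of
#'   the health-coupled traits. The default 0 makes every continuous trait's
#'   exposure a deterministic function of the sample (q = 1 + h for coupled
#'   traits, q = 1 for age-only traits), so that all per-sample variation
#'   flows through the shared health factor and the binary status; set > 0 to
#'   add trait-specific exposure noise on top.
#' @return A list with elements `traits` (61-row trait table), `sites`
#'   (site table) and `health_sd`.
#' @export
#' @examples
#' d <- benchmark_design(binary_q = 0.995, seed = 1)
#' nrow(d$traits)  # 61
#' nrow(d$sites)   # 400
benchmark_design <- function(binary_q = 0.995, health_sd = 0, seed = 1,
                          n_total_sites = 400, age_range = c(0, 100),
                          sample_effect_sd = 0) {
  if (binary_q < 0.995 || binary_q > 1) {
    stop("`binary_q` must lie in [0.995, 1]", call. = FALSE)
  }
  cont <- dplyr::bind_rows(
    purrr::map_dfr(1:10, ~ trait_spec(0.5, 0.01, q_sd = sample_effect_sd, health_coupled = TRUE)),
    purrr::map_dfr(1:10, ~ trait_spec(1.0, 0.01, q_sd = sample_effect_sd, health_coupled = TRUE)),
    purrr::map_dfr(1:20, ~ trait_spec(0.5, 0.01, q_sd = 0)),
    purrr::map_dfr(1:20, ~ trait_spec(1.0, 0.01, q_sd = 0))
  )
  cont$trait_id <- sprintf("t%02d", seq_len(nrow(cont)))
  bin <- trait_spec(0.5, 0, binary = TRUE, binary_q = binary_q,
                    binary_prob = 0.5, trait_id = "bin1")
  traits <- dplyr::bind_rows(cont, bin)

  w_single <- purrr::map(rep(cont$trait_id, each = 5), ~ stats::setNames(1, .x))
  w_binary <- purrr::map(1:50, ~ stats::setNames(1, "bin1"))
  w_mix <- purrr::map(1:50, function(i) {
    picks <- with_substream(substream_seed(seed, "mixture", i),
                            sample(cont$trait_id, 4))
    stats::setNames(rep(0.2, 5), c(picks, "bin1"))
  })
  weight_list <- c(w_single, w_binary, w_mix)

  n_base <- length(weight_list)
  if (n_total_sites < n_base) {
    stop("`n_total_sites` must be >= the enumerated ", n_base, " sites", call. = FALSE)
  }
  if (n_total_sites > n_base) {
    extra_ids <- rep_len(cont$trait_id, n_total_sites - n_base)
    weight_list <- c(weight_list, purrr::map(extra_ids, ~ stats::setNames(1, .x)))
  }

  sites <- random_sites(weight_list, traits, age_range = age_range, seed = seed)
  list(traits = traits, sites = sites, health_sd = health_sd)
}

#' Simulate compositional cell-type abundance fractions
#'
#' A synthetic stand-in for array-derived blood cell-type abundance
#' estimates: per-sample fractions are drawn from a Dirichlet distribution
#' whose concentration parameters drift log-linearly with age at rate
#' `age_drift` (alternating sign across cell types), emulating age-associated
#' shifts in blood composition. With `age_drift = 0` the fractions are
#' age-independent.
#'
#' @param cohort Cohort tibble (uses its `age` column and sample order).
#' @param n_types Number of cell types (>= 2).
#' @param age_drift Per-year log-concentration drift.
#' @param seed Integer seed.
#' @return Matrix of fractions, samples in rows (rownames `sample_id`),
#'   cell types `ct1..ctK` in columns; each row sums to 1.
#' @export
simulate_celltype_fractions <- function(cohort, n_types = 6, age_drift = 0,
                                        seed = 1) {
  stopifnot(n_types >= 2)
  n <- nrow(cohort)
  base <- 2 + 6 * (n_types:1) / n_types
  dir_sign <- rep_len(c(1, -1), n_types)
  with_substream(substream_seed(seed, "celltypes"), {
    out <- matrix(0, n, n_types,
                  dimnames = list(cohort$sample_id, paste0("ct", seq_len(n_types))))
    for (t in seq_len(n_types)) {
      conc <- base[t] * exp(dir_sign[t] * age_drift * cohort$age)
      out[, t] <- stats::rgamma(n, shape = conc, rate = 1)
    }
    out / rowSums(out)
  })
}

#' Split a matrix and cohort into random halves
#'
#' Randomly partitions the samples into disjoint, exhaustive train and test
#' halves whose sizes differ by at most one; deterministic for a fixed seed.
#'
#' @param matrix Sites-by-samples beta matrix (columns in cohort order).
#' @param cohort Cohort tibble with matching `sample_id`s.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, each a list of `matrix`
#'   (column subset) and `cohort` (row subset).
#' @export
split_half <- function(matrix, cohort, seed = 1) {
  n <- nrow(cohort)
  stopifnot(n >= 4, ncol(matrix) == n)
  perm <- with_substream(substream_seed(seed, "split"), sample.int(n))
  n_train <- ceiling(n / 2)
  tr <- sort(perm[seq_len(n_train)])
  te <- sort(perm[-seq_len(n_train)])
  list(
    train = list(matrix = matrix[, tr, drop = FALSE], cohort = cohort[tr, ]),
    test = list(matrix = matrix[, te, drop = FALSE], cohort = cohort[te, ])
  )
}
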