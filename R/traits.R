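#' Define a simulated age-associated trait
#'
#' A trait (phenotype) contributes to the latent epigenetic state of a sample
#' as \eqn{p_{k,j} = \mathrm{Age}_j^{\gamma_k} \, q_{k,j}}. The exponent
#' \eqn{\gamma_k} is a characteristic of the trait, drawn once per trait from
#' \eqn{N(\mu_\gamma, \sigma_\gamma^2)}; the exposure \eqn{q_{k,j}} is drawn
#' once per sample per trait. \eqn{\gamma = 1} gives a trait linear in age,
#' \eqn{0 < \gamma < 1} a non-linear (e.g. square-root) trait, and
#' \eqn{\gamma = 0} an age-independent trait (\eqn{p = q}).
#'
#' For a health-coupled trait the per-sample exposure distribution is shifted
#' by the sample's latent health value: \eqn{q \sim N(q_{mean} + h_j,
#' q_{sd}^2)}. For a binary trait the exposure takes exactly two values:
#' `binary_q` with probability `binary_prob` ("exposed"/"on") and 1 otherwise.
#' Exposures below 1 decelerate, above 1 accelerate, the trait's contribution
#' to epigenetic aging.
#'
#' @param gamma_mean Mean of the trait exponent \eqn{\gamma_k} (dimensionless).
#' @param gamma_sd Standard deviation of the trait exponent; 0 fixes
#'   \eqn{\gamma_k} at `gamma_mean`.
#' @param q_mean Mean per-sample exposure (dimensionless; 1 = neutral).
#' @param q_sd Standard deviation of the per-sample exposure.
#' @param health_coupled If `TRUE`, the exposure mean is shifted by the
#'   sample's health value \eqn{h_j}.
#' @param binary If `TRUE`, the exposure is two-valued (`binary_q` or 1).
#' @param binary_q Exposure value when the binary trait is "on".
#' @param binary_prob Probability the binary trait is "on", in `[0, 1]`.
#' @param trait_id Optional identifier; autogenerated when combined in designs.
#' @return A one-row tibble describing the trait; bind rows to build designs.
#' @export
#' @examples
#' trait_spec(gamma_mean = 0.5, gamma_sd = 0.01, q_sd = 0.05,
#'            health_coupled = TRUE)
#' trait_spec(gamma_mean = 0.5, binary = TRUE, binary_q = 0.995)
trait_spec <- function(gamma_mean,
                       gamma_sd = 0,
                       q_mean = 1,
                       q_sd = 0,
                       health_coupled = FALSE,
                       binary = FALSE,
                       binary_q = 1,
                       binary_prob = 0.5,
                       trait_id = NA_character_) {
  stopifnot(is.numeric(gamma_mean), length(gamma_mean) == 1L)
  if (gamma_sd < 0) stop("`gamma_sd` must be >= 0", call. = FALSE)
  if (q_sd < 0) stop("`q_sd` must be >= 0", call. = FALSE)
  if (binary_prob < 0 || binary_prob > 1) {
    stop("`binary_prob` must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    trait_id = trait_id,
    gamma_mean = as.double(gamma_mean),
    gamma_sd = as.double(gamma_sd),
    q_mean = as.double(q_mean),
    q_sd = as.double(q_sd),
    health_coupled = isTRUE(health_coupled),
    binary = isTRUE(binary),
    binary_q = as.double(binary_q),
    binary_prob = as.double(binary_prob)
  )
}

# Draw the trait exponent gamma_k (one draw per trait, shared by all samples).
draw_gamma <- function(trait, seed) {
  if (trait$gamma_sd == 0) {
    trait$gamma_mean
  } else {
    with_substream(seed, stats::rnorm(1, trait$gamma_mean, trait$gamma_sd))
  }
}

# Draw per-sample exposures q_{k,j} for one trait. `health` is the vector of
# per-sample h_j; for binary traits it is ignored and the draw is two-valued.
draw_q <- function(trait, health, seed) {
  n <- length(health)
  with_substream(seed, {
    if (trait$binary) {
      on <- stats::runif(n) < trait$binary_prob
      ifelse(on, trait$binary_q, 1)
    } else {
      mu <- trait$q_mean + if (trait$health_coupled) health else 0
      stats::rnorm(n, mu, trait$q_sd)
    }
  })
}

#' Realize a trait's phenotype values for samples
#'
#' Computes \eqn{p_{k,j} = \mathrm{Age}_j^{\gamma_k} q_{k,j}}, drawing one
#' \eqn{\gamma_k} for the trait and one exposure \eqn{q_{k,j}} per sample.
#' With \eqn{\gamma_k = 0} the phenotype equals the exposure draw and is
#' age-independent.
#'
#' @param trait A one-row tibble from [trait_spec()].
#' @param age Vector of non-negative ages (years).
#' @param health Vector of per-sample health values \eqn{h_j} (recycled if
#'   scalar); shifts the exposure mean for health-coupled traits.
#' @param seed Integer seed for the trait's gamma and exposure draws.
#' @return A tibble with columns `phenotype`, `q` and the realized `gamma`.
#' @export
#' @examples
#' tr <- trait_spec(gamma_mean = 0.5)
#' realize_phenotype(tr, age = c(25, 100), health = 0, seed = 1)
realize_phenotype <- function(trait, age, health = 0, seed = 1) {
  if (any(age < 0)) {
    stop("ages must be non-negative (fractional powers of negative ages are undefined)",
         call. = FALSE)
  }
  health <- rep_len(health, length(age))
  gamma <- draw_gamma(trait, substream_seed(seed, "gamma"))
  q <- draw_q(trait, health, substream_seed(seed, "q"))
  p <- if (gamma == 0) q else age^gamma * q
  tibble::tibble(phenotype = p, q = q, gamma = gamma)
}
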