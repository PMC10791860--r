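#' Fit per-site linear methylation models against a state vector
#'
#' Ordinary least squares of each site's methylation values on the per-sample
#' states: \eqn{\hat m_{ij} = m^0_i + r_i s_j + \epsilon_{ij}}. This is the
#' "expectation" half of the pacemaker's conditional EM iteration (states
#' held fixed, site parameters updated).
#'
#' @param matrix Sites-by-samples beta matrix.
#' @param states Per-sample state vector (non-constant), e.g. ages on the
#'   first iteration.
#' @return A list with numeric vectors `m0` (per-site intercepts) and
#'   `rates` (per-site slopes).
#' @export
fit_site_models <- function(matrix, states) {
  stopifnot(ncol(matrix) == length(states))
  sc <- states - mean(states)
  denom <- sum(sc^2)
  if (denom == 0) stop("states are constant; per-site slopes are undefined", call. = FALSE)
  rates <- as.vector(matrix %*% sc) / denom
  m0 <- unname(rowMeans(matrix)) - rates * mean(states)
  list(m0 = m0, rates = rates)
}

#' Update per-sample epigenetic states given site models
#'
#' The "maximization" half of the conditional EM iteration: with site
#' intercepts and rates held fixed, each sample's state is set to the exact
#' least-squares minimizer of its methylation residuals,
#' \deqn{s_j = \frac{\sum_i r_i (\hat m_{ij} - m^0_i)}{\sum_i r_i^2}.}
#'
#' @param matrix Sites-by-samples beta matrix.
#' @param m0 Per-site intercepts.
#' @param rates Per-site rates; must not be all zero.
#' @return Numeric vector of states, one per sample.
#' @export
update_states <- function(matrix, m0, rates) {
  stopifnot(nrow(matrix) == length(m0), length(m0) == length(rates))
  r2 <- sum(rates^2)
  if (r2 == 0) stop("all site rates are zero; the state update is undefined", call. = FALSE)
  as.vector(crossprod(rates, matrix - m0)) / r2
}

#' Fit the epigenetic pacemaker by conditional expectation maximization
#'
#' Models each site's methylation as linear in a shared latent per-sample
#' epigenetic state, \eqn{\hat m_{ij} = m^0_i + r_i s_j + \epsilon_{ij}}, and
#' minimizes the total squared methylation error by coordinate descent:
#' states are initialized at the chronological ages, site models are fit per
#' site by OLS, states are then updated to their closed-form least-squares
#' minimizers, and the two steps alternate until the relative reduction in
#' total squared error falls below `tol` or `max_iter` is reached. The age
#' initialization anchors the scale of the states (the model is otherwise
#' identifiable only up to an affine transform), so fitted states are
#' year-like but may be non-linear in age.
#'
#' @param matrix Sites-by-samples beta matrix; complete (no missing values),
#'   at least 2 sites and 3 samples.
#' @param ages Per-sample chronological ages (years), non-constant; used to
#'   initialize the states.
#' @param tol Relative error-reduction threshold for convergence.
#' @param max_iter Maximum number of EM iterations.
#' @return An object of class `"epm"`: a list with `m0`, `rates` (per site),
#'   `states` (per sample), `ages`, `n_iter`, `error_trace` (total squared
#'   error after each iteration, non-increasing), `converged`, `site_ids`,
#'   `sample_ids`. Supports [predict()][predict.epm], [tidy()][tidy.epm],
#'   [glance()][glance.epm] and [ggplot2::autoplot()][autoplot.epm].
#' @export
#' @examples
#' ages <- seq(1, 80, length.out = 40)
#' m <- rbind(0.2 + 0.004 * ages, 0.9 - 0.006 * ages)
#' fit <- fit_epm(m, ages)
#' fit$n_iter
fit_epm <- function(matrix, ages, tol = 1e-4, max_iter = 100) {
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix))) stop("matrix contains non-finite values", call. = FALSE)
  if (nrow(matrix) < 2) stop("need at least 2 sites", call. = FALSE)
  if (ncol(matrix) < 3) stop("need at least 3 samples", call. = FALSE)
  stopifnot(length(ages) == ncol(matrix))
  if (stats::var(ages) == 0) stop("ages are constant", call. = FALSE)
  stopifnot(tol > 0, max_iter >= 1)

  states <- as.double(ages)
  trace <- numeric(0)
  m0 <- rates <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    site <- fit_site_models(matrix, states)
    m0 <- site$m0
    rates <- site$rates
    states <- update_states(matrix, m0, rates)
    sse <- sum((matrix - (m0 + rates %o% states))^2)
    trace <- c(trace, sse)
    if (it > 1 && (trace[it - 1] - sse) <= tol * trace[it - 1]) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      m0 = m0, rates = rates, states = states, ages = as.double(ages),
      n_iter = length(trace), error_trace = trace, converged = converged,
      tol = tol, max_iter = max_iter,
      site_ids = rownames(matrix), sample_ids = colnames(matrix)
    ),
    class = "epm"
  )
}

#' Predict epigenetic states for new samples
#'
#' Applies one closed-form state update with the fitted site intercepts and
#' rates held fixed; each new sample's state is independent of the others.
#'
#' @param model An `"epm"` fit.
#' @param matrix_new Beta matrix for new samples containing the model's sites
#'   (matched by rowname when present, otherwise positionally).
#' @return Numeric vector of states, one per column of `matrix_new`.
#' @export
predict_states <- function(model, matrix_new) {
  stopifnot(inherits(model, "epm"))
  matrix_new <- as.matrix(matrix_new)
  if (!is.null(model$site_ids) && !is.null(rownames(matrix_new))) {
    missing <- setdiff(model$site_ids, rownames(matrix_new))
    if (length(missing)) {
      stop("matrix is missing model site(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    matrix_new <- matrix_new[model$site_ids, , drop = FALSE]
  } else if (nrow(matrix_new) != length(model$m0)) {
    stop("matrix has ", nrow(matrix_new), " sites; model expects ",
         length(model$m0), call. = FALSE)
  }
  update_states(matrix_new, model$m0, model$rates)
}

#' @export
predict.epm <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$states)
  predict_states(object, newdata)
}

#' Total squared and mean absolute methylation error of an EPM model
#'
#' @param matrix Sites-by-samples beta matrix.
#' @param model An `"epm"` fit (or any list with `m0`, `rates`, `states`).
#' @param states Optional states overriding `model$states` (e.g. predicted
#'   states for a test matrix).
#' @return A tibble with columns `sse` and `mae` (beta units).
#' @export
model_error <- function(matrix, model, states = NULL) {
  states <- states %||% model$states
  stopifnot(nrow(matrix) == length(model$m0), ncol(matrix) == length(states))
  resid <- matrix - (model$m0 + model$rates %o% states)
  tibble::tibble(sse = sum(resid^2), mae = mean(abs(resid)))
}

#' Map epigenetic states to years ("EPM age")
#'
#' The pacemaker's states are year-like (anchored by the age initialization)
#' but may be non-linear in age. For reporting prediction error in years, a
#' trend \eqn{s = a + b\,\mathrm{age} + c\sqrt{\mathrm{age}}} is fit on
#' training data and inverted numerically (monotone grid inversion over the
#' training age range) to convert states to years.
#'
#' @param states Training states.
#' @param ages Training ages (years).
#' @return An object of class `"state_age_map"`; use `predict(map, states)`
#'   to convert states to years.
#' @export
fit_state_age_map <- function(states, ages) {
  stopifnot(length(states) == length(ages), length(ages) >= 3)
  fit <- stats::lm(states ~ ages + sqrt(ages))
  grid_age <- seq(max(min(ages), 0), max(ages) * 1.2 + 1, length.out = 20001)
  grid_state <- stats::predict(fit, list(ages = grid_age))
  keep <- !duplicated(grid_state)
  structure(
    list(coef = stats::coef(fit), grid_age = grid_age[keep],
         grid_state = grid_state[keep]),
    class = "state_age_map"
  )
}

#' @export
predict.state_age_map <- function(object, states, ...) {
  ord <- order(object$grid_state)
  stats::approx(object$grid_state[ord], object$grid_age[ord],
                xout = states, rule = 2)$y
}

#' @rdname fit_epm
#' @param x,object An `"epm"` fit.
#' @param what For `tidy()`: `"sites"` returns per-site intercepts and rates,
#'   `"samples"` returns per-sample states.
#' @param ... Unused.
#' @method tidy epm
#' @export
tidy.epm <- function(x, what = c("sites", "samples"), ...) {
  what <- match.arg(what)
  if (what == "sites") {
    tibble::tibble(
      site_id = x$site_ids %||% sprintf("site%04d", seq_along(x$m0)),
      m0 = x$m0, rate = x$rates
    )
  } else {
    tibble::tibble(
      sample_id = x$sample_ids %||% sprintf("s%04d", seq_along(x$states)),
      age = x$ages, state = x$states
    )
  }
}

#' @rdname fit_epm
#' @method glance epm
#' @export
glance.epm <- function(x, ...) {
  tibble::tibble(
    n_sites = length(x$m0), n_samples = length(x$states),
    n_iter = x$n_iter, converged = x$converged,
    sse = x$error_trace[x$n_iter],
    mae = mean(abs(x$states - x$ages))
  )
}

#' @export
print.epm <- function(x, ...) {
  cat("Epigenetic pacemaker fit\n")
  cat("  sites:", length(x$m0), " samples:", length(x$states), "\n")
  cat("  iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  final SSE:", format(x$error_trace[x$n_iter], digits = 6), "\n")
  invisible(x)
}

#' @rdname fit_epm
#' @method autoplot epm
#' @export
autoplot.epm <- function(object, ...) {
  d <- tidy.epm(object, "samples")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$state)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(formula = y ~ x + sqrt(x), method = "lm",
                         se = FALSE, linewidth = 0.6, colour = "firebrick") +
    ggplot2::labs(x = "Chronological age (years)",
                  y = "Epigenetic state",
                  title = "Epigenetic pacemaker states vs age")
}
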