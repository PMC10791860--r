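#' Fit an elastic-net epigenetic clock
#'
#' The comparator model: penalized regression of chronological age on
#' methylation beta values,
#' \deqn{L(\lambda_1, \lambda_2, \beta) = |y - X\beta|^2 + \lambda_2 |\beta|^2
#'   + \lambda_1 |\beta|,}
#' solved by glmnet with mixing parameter `l1_ratio` (the elastic-net
#' `alpha`). The penalty strength is either chosen by k-fold cross-validation
#' (`penalty = "cv"`, the default, minimizing CV mean squared error) or fixed
#' at a given total penalty (`penalty = 1` reproduces the common
#' scikit-learn-style `ElasticNet(alpha = 1)` objective; predictors are not
#' standardized, matching that convention).
#'
#' @param matrix Sites-by-samples beta matrix (transposed internally to the
#'   samples-by-sites design).
#' @param ages Per-sample ages (years).
#' @param cv_folds Folds for the cross-validated penalty path.
#' @param l1_ratio Elastic-net mixing parameter in `(0, 1]`; 0.75 by default.
#' @param seed Integer seed (fold assignment and any solver randomness).
#' @param penalty `"cv"` or a positive number fixing the total penalty.
#' @return An object of class `"epi_clock"` with elements `intercept`,
#'   `coefficients` (named per site), `lambda`, `l1_ratio`, `cv_folds`,
#'   `site_ids`. Supports [predict()][predict.epi_clock], `tidy()` and
#'   `glance()`.
#' @export
fit_clock <- function(matrix, ages, cv_folds = 5, l1_ratio = 0.75, seed = 1,
                      penalty = "cv") {
  x <- t(as.matrix(matrix))
  n <- nrow(x)
  stopifnot(length(ages) == n)
  if (identical(penalty, "cv") && n < cv_folds) {
    stop("need at least `cv_folds` (", cv_folds, ") samples, got ", n, call. = FALSE)
  }
  if (identical(penalty, "cv")) {
    foldid <- with_substream(substream_seed(seed, "clock-folds"),
                             sample(rep_len(seq_len(cv_folds), n)))
    cvfit <- glmnet::cv.glmnet(x, ages, alpha = l1_ratio, foldid = foldid,
                               standardize = FALSE)
    lambda <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
    cv_mse <- cvfit$cvm[cvfit$lambda == lambda]
    beta <- as.vector(glmnet::coef.glmnet(fit, s = lambda))
  } else {
    stopifnot(is.numeric(penalty), penalty > 0)
    # `penalty` is the total penalty `a` of the objective
    #   1/(2n) |y - Xb|^2 + a*l1 |b|_1 + a*(1-l1)/2 |b|^2.
    # glmnet rescales the response internally, which changes the L1 and L2
    # parts differently; solving on the pre-standardized response with a
    # transformed (lambda, alpha) recovers the stated objective exactly
    # (coefficients then scale back by the response sd).
    sy <- sqrt(mean((ages - mean(ages))^2))
    lam_l1 <- penalty * l1_ratio / sy
    lam_l2 <- penalty * (1 - l1_ratio)
    alpha_g <- lam_l1 / (lam_l1 + lam_l2)
    lambda_g <- lam_l1 + lam_l2
    fit <- glmnet::glmnet(x, ages / sy, alpha = alpha_g,
                          lambda = lambda_g * c(16, 8, 4, 2, 1),
                          standardize = FALSE, thresh = 1e-12)
    beta <- as.vector(glmnet::coef.glmnet(fit, s = lambda_g)) * sy
    lambda <- penalty
    cv_mse <- NA_real_
  }
  structure(
    list(
      intercept = beta[1],
      coefficients = stats::setNames(beta[-1], colnames(x)),
      lambda = lambda, l1_ratio = l1_ratio,
      cv_folds = if (identical(penalty, "cv")) cv_folds else NA_integer_,
      cv_mse = cv_mse, site_ids = colnames(x), fit = fit
    ),
    class = "epi_clock"
  )
}

#' Predict ages from a fitted epigenetic clock
#'
#' @param model An `"epi_clock"` fit.
#' @param matrix_new Beta matrix (sites x samples) containing the model's
#'   sites (matched by rowname when present, otherwise positionally).
#' @return Numeric vector of predicted ages (years), one per sample.
#' @export
predict_age <- function(model, matrix_new) {
  stopifnot(inherits(model, "epi_clock"))
  matrix_new <- as.matrix(matrix_new)
  if (!is.null(model$site_ids) && !is.null(rownames(matrix_new))) {
    missing <- setdiff(model$site_ids, rownames(matrix_new))
    if (length(missing)) {
      stop("matrix is missing clock site(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    matrix_new <- matrix_new[model$site_ids, , drop = FALSE]
  } else if (nrow(matrix_new) != length(model$coefficients)) {
    stop("matrix has ", nrow(matrix_new), " sites; clock expects ",
         length(model$coefficients), call. = FALSE)
  }
  as.vector(model$intercept + crossprod(matrix_new, model$coefficients))
}

#' @export
predict.epi_clock <- function(object, newdata, ...) {
  predict_age(object, newdata)
}

#' Age-prediction accuracy metrics
#'
#' Coefficient of determination \eqn{R^2 = 1 - \sum(y - \hat y)^2 /
#' \sum(y - \bar y)^2} and mean absolute error in years.
#'
#' @param true_ages Observed ages.
#' @param predictions Predicted ages (same length).
#' @return A tibble with columns `r_squared` and `mae`.
#' @export
#' @examples
#' fit_metrics(c(0, 10), c(1, 9))  # R^2 = 0.96, MAE = 1
fit_metrics <- function(true_ages, predictions) {
  stopifnot(length(true_ages) == length(predictions), length(true_ages) >= 2)
  ss_tot <- sum((true_ages - mean(true_ages))^2)
  if (ss_tot == 0) stop("true ages are constant; R^2 is undefined", call. = FALSE)
  tibble::tibble(
    r_squared = 1 - sum((true_ages - predictions)^2) / ss_tot,
    mae = mean(abs(true_ages - predictions))
  )
}

#' @method tidy epi_clock
#' @export
tidy.epi_clock <- function(x, ...) {
  keep <- x$coefficients != 0
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)[keep]),
    estimate = c(x$intercept, unname(x$coefficients[keep]))
  )
}

#' @method glance epi_clock
#' @export
glance.epi_clock <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, l1_ratio = x$l1_ratio, cv_folds = x$cv_folds,
    cv_mse = x$cv_mse, n_sites = length(x$coefficients),
    n_nonzero = sum(x$coefficients != 0)
  )
}

#' @export
print.epi_clock <- function(x, ...) {
  cat("Elastic-net epigenetic clock\n")
  cat("  sites:", length(x$coefficients),
      " nonzero:", sum(x$coefficients != 0), "\n")
  cat("  lambda:", format(x$lambda, digits = 4),
      " l1_ratio:", x$l1_ratio, "\n")
  invisible(x)
}
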