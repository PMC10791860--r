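#' Principal components of cell-type abundance fractions
#'
#' Reduces estimated cell-type abundances to three principal components fit
#' on training samples only; the trained rotation is then applied to test and
#' validation samples so that all moderation models share one covariate
#' basis.
#'
#' @param fractions_train Samples-by-cell-types matrix of abundance fractions
#'   (>= 4 samples, >= 3 cell types, rank >= 3 after centering).
#' @return An object of class `"celltype_pca"`; `predict(pca, fractions)`
#'   returns a samples-by-3 matrix of component scores `PC1..PC3`.
#' @export
fit_celltype_pca <- function(fractions_train) {
  fractions_train <- as.matrix(fractions_train)
  if (nrow(fractions_train) < 4) stop("need at least 4 samples", call. = FALSE)
  if (ncol(fractions_train) < 3) stop("need at least 3 cell types", call. = FALSE)
  pc <- stats::prcomp(fractions_train, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > max(pc$sdev) * 1e-8) < 3) {
    stop("cell-type fractions have rank < 3; cannot extract 3 components",
         call. = FALSE)
  }
  structure(
    list(rotation = pc$rotation[, 1:3, drop = FALSE],
         center = pc$center, sdev = pc$sdev),
    class = "celltype_pca"
  )
}

#' @export
predict.celltype_pca <- function(object, fractions, ...) {
  fractions <- as.matrix(fractions)
  if (is.null(dim(fractions)) || ncol(fractions) != length(object$center)) {
    stop("fractions must have ", length(object$center), " cell-type columns",
         call. = FALSE)
  }
  scores <- sweep(fractions, 2, object$center) %*% object$rotation
  colnames(scores) <- c("PC1", "PC2", "PC3")
  scores
}

#' Build the moderation design matrix
#'
#' Assembles the standard moderation predictors: age, the square root of age
#' (absorbing the non-linear association between age and the epigenetic
#' state), any additional covariates in declared order (e.g. a continuous
#' health factor and a binary status in simulation mode, or cell-type PCs
#' 1-3 in real-data mode), and a 0/1 sex term. If the proportion of female
#' samples exceeds `female_drop_threshold`, the sex term is dropped (a
#' heavily female-skewed batch cannot inform a sex effect) and the decision
#' is recorded.
#'
#' @param ages Non-negative ages (years).
#' @param covariates Optional named list or data frame of numeric per-sample
#'   covariates.
#' @param sex_labels Optional sex labels: a 0/1/logical female indicator or a
#'   character/factor vector in which `"female"`/`"f"` (case-insensitive)
#'   marks female samples.
#' @param female_drop_threshold Female-proportion threshold above which the
#'   sex term is dropped.
#' @return A tibble of predictor columns (`age`, `sqrt_age`, covariates,
#'   optionally `sex`) with attribute `"sex_dropped"` (`TRUE`/`FALSE`/`NA`
#'   when no sex labels were supplied). Constant (zero-variance) covariates
#'   cannot enter an OLS fit alongside the intercept and are dropped with a
#'   message; their names are recorded in attribute `"dropped_terms"`. The
#'   intercept is added at fit time.
#' @export
#' @examples
#' build_design(c(25, 49, 64))
build_design <- function(ages, covariates = NULL, sex_labels = NULL,
                         female_drop_threshold = 0.7) {
  if (any(ages < 0)) stop("ages must be non-negative", call. = FALSE)
  design <- tibble::tibble(age = as.double(ages), sqrt_age = sqrt(ages))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(ages))
    for (nm in names(covariates)) {
      if (!is.numeric(covariates[[nm]])) {
        stop("covariate `", nm, "` is not numeric", call. = FALSE)
      }
      design[[nm]] <- covariates[[nm]]
    }
  }
  dropped <- character()
  for (nm in setdiff(names(design), c("age", "sqrt_age"))) {
    if (stats::var(design[[nm]]) == 0) {
      dropped <- c(dropped, nm)
      design[[nm]] <- NULL
    }
  }
  if (length(dropped)) {
    message("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
  }
  sex_dropped <- NA
  if (!is.null(sex_labels)) {
    stopifnot(length(sex_labels) == length(ages))
    female <- if (is.numeric(sex_labels) || is.logical(sex_labels)) {
      as.numeric(sex_labels) > 0
    } else {
      tolower(as.character(sex_labels)) %in% c("female", "f")
    }
    if (mean(female) > female_drop_threshold) {
      sex_dropped <- TRUE
    } else {
      sex_dropped <- FALSE
      design$sex <- as.double(female)
    }
  }
  attr(design, "sex_dropped") <- sex_dropped
  attr(design, "dropped_terms") <- dropped
  design
}

#' Fit a moderation regression of an epigenetic outcome
#'
#' Ordinary least squares of a per-sample epigenetic outcome (pacemaker
#' state or clock-predicted age) on a [build_design()] matrix, with classical
#' standard errors and two-sided t-test p-values per term. A term whose
#' p-value is small identifies a moderator of the age-epigenome association.
#'
#' @param outcome Per-sample outcome values.
#' @param design Predictor tibble from [build_design()].
#' @param outcome_label Label stored with the result (e.g. `"epm_state"` or
#'   `"clock_age"`).
#' @return An object of class `"moderation_fit"`; `tidy()` gives the term
#'   table (`term`, `estimate`, `std.error`, `statistic`, `p.value`),
#'   `glance()` the fit summary.
#' @export
fit_moderation <- function(outcome, design, outcome_label = "outcome") {
  stopifnot(length(outcome) == nrow(design))
  p <- ncol(design) + 1L
  if (length(outcome) <= p + 1L) {
    stop("need more samples (", length(outcome), ") than terms + 1 (", p + 1L,
         ")", call. = FALSE)
  }
  dat <- as.data.frame(design)
  dat$.outcome <- as.double(outcome)
  fit <- stats::lm(.outcome ~ ., data = dat)
  if (fit$rank < p) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("design is rank deficient; collinear term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  structure(
    list(fit = fit, outcome_label = outcome_label,
         n_samples = length(outcome),
         sex_term_dropped = isTRUE(attr(design, "sex_dropped"))),
    class = "moderation_fit"
  )
}

#' @method tidy moderation_fit
#' @export
tidy.moderation_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    outcome = x$outcome_label,
    term = rownames(s),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @method glance moderation_fit
#' @export
glance.moderation_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    outcome = x$outcome_label, n_samples = x$n_samples,
    r_squared = s$r.squared, sigma = s$sigma,
    sex_term_dropped = x$sex_term_dropped
  )
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat("Moderation fit (", x$outcome_label, "), n = ", x$n_samples,
      if (x$sex_term_dropped) ", sex term dropped" else "", "\n", sep = "")
  print(tidy.moderation_fit(x))
  invisible(x)
}

#' Count significant moderator effects across models
#'
#' Summarizes a collection of moderation fits: for each term, in how many
#' models is its p-value below the significance threshold. The threshold is
#' `alpha`, or `alpha / n_models_for_bonferroni` when a Bonferroni divisor is
#' given (e.g. `0.05 / 13 = 0.00385`).
#'
#' @param results List of `"moderation_fit"` objects (or tibbles from
#'   `tidy()` on them).
#' @param alpha Base significance level.
#' @param n_models_for_bonferroni Optional Bonferroni divisor.
#' @return A tibble with columns `term`, `n_significant`, `n_models`,
#'   `threshold`.
#' @export
significance_summary <- function(results, alpha = 0.05,
                                 n_models_for_bonferroni = NULL) {
  threshold <- if (is.null(n_models_for_bonferroni)) {
    alpha
  } else {
    alpha / n_models_for_bonferroni
  }
  tidied <- purrr::map_dfr(results, function(r) {
    if (inherits(r, "moderation_fit")) tidy.moderation_fit(r) else tibble::as_tibble(r)
  })
  if (nrow(tidied) == 0) {
    return(tibble::tibble(term = character(), n_significant = integer(),
                          n_models = integer(), threshold = double()))
  }
  tidied |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      n_significant = sum(.data$p.value < threshold),
      n_models = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(threshold = threshold)
}
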