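#' Filter sites by absolute Pearson correlation with age
#'
#' Retains sites whose methylation correlates with chronological age beyond a
#' threshold (`|PCC| > threshold`); the first screen of the model-building
#' pipeline. Zero-variance sites have an undefined correlation, are treated
#' as 0 and excluded (a message reports how many).
#'
#' @param matrix Sites-by-samples beta matrix with site rownames.
#' @param ages Per-sample ages (non-constant).
#' @param threshold Absolute-correlation cutoff (e.g. 0.4 or 0.45).
#' @return A tibble of retained sites with columns `site_id` and `pcc`.
#' @export
pcc_filter <- function(matrix, ages, threshold = 0.4) {
  stopifnot(ncol(matrix) == length(ages))
  if (stats::var(ages) == 0) stop("ages are constant", call. = FALSE)
  sds <- apply(matrix, 1, stats::sd)
  zero_var <- sds == 0
  pcc <- rep(0, nrow(matrix))
  if (any(!zero_var)) {
    ac <- ages - mean(ages)
    mc <- matrix[!zero_var, , drop = FALSE] - rowMeans(matrix[!zero_var, , drop = FALSE])
    pcc[!zero_var] <- as.vector(mc %*% ac) /
      (sqrt(rowSums(mc^2)) * sqrt(sum(ac^2)))
  }
  if (any(zero_var)) {
    message(sum(zero_var), " zero-variance site(s) excluded from the PCC filter")
  }
  keep <- abs(pcc) > threshold
  tibble::tibble(
    site_id = rownames(matrix)[keep] %||% which(keep),
    pcc = unname(pcc[keep])
  )
}

#' Screen sites by linear-in-age prediction error
#'
#' For each site, fits OLS of methylation on age and retains sites whose mean
#' absolute error is below `mae_threshold` (beta units). The per-site
#' residual vectors are kept for residual-shape clustering.
#'
#' @param matrix Sites-by-samples beta matrix (typically already
#'   PCC-filtered).
#' @param ages Per-sample ages.
#' @param mae_threshold MAE cutoff in beta units (default 0.025).
#' @return A tibble of passing sites: `site_id`, `linfit_intercept`,
#'   `linfit_slope`, `mae`, and `residuals` (list-column of per-sample
#'   residual vectors).
#' @export
mae_screen <- function(matrix, ages, mae_threshold = 0.025) {
  stopifnot(ncol(matrix) == length(ages))
  fit <- fit_site_models(matrix, ages)
  resid <- matrix - (fit$m0 + fit$rates %o% as.double(ages))
  mae <- unname(rowMeans(abs(resid)))
  keep <- mae < mae_threshold
  tibble::tibble(
    site_id = rownames(matrix)[keep] %||% which(keep),
    linfit_intercept = fit$m0[keep],
    linfit_slope = fit$rates[keep],
    mae = mae[keep],
    residuals = purrr::map(which(keep), ~ unname(resid[.x, ]))
  )
}

#' Remove low-variance sites
#'
#' Retains sites whose sample variance is at least `min_variance`; the
#' preprocessing step of the full elastic-net clock branch.
#'
#' @param matrix Sites-by-samples beta matrix.
#' @param min_variance Variance cutoff (default 0.001).
#' @return Character vector of retained site ids.
#' @export
variance_filter <- function(matrix, min_variance = 0.001) {
  v <- apply(matrix, 1, stats::var)
  ids <- rownames(matrix) %||% as.character(seq_len(nrow(matrix)))
  ids[v >= min_variance]
}

#' Cluster sites by the shape of their age-regression residuals
#'
#' Sites whose methylation departs from the linear-in-age fit in the same
#' way (the same residual shape across training samples) are grouped by
#' affinity propagation on the negative squared Euclidean distance between
#' residual vectors.
#'
#' @param screens Tibble from [mae_screen()] (needs `site_id` and the
#'   `residuals` list-column).
#' @param preference Affinity-propagation preference (default -2.5).
#' @param seed Integer seed (tie-breaking jitter).
#' @param damping,max_iter Passed to [affinity_propagation()].
#' @return A tibble with columns `site_id` and `cluster` (integer labels).
#' @export
cluster_residuals <- function(screens, preference = -2.5, seed = 1,
                              damping = 0.9, max_iter = 1000) {
  stopifnot(nrow(screens) >= 2)
  resid <- do.call(rbind, screens$residuals)
  d2 <- as.matrix(stats::dist(resid))^2
  ap <- affinity_propagation(-d2, preference = preference, damping = damping,
                             max_iter = max_iter, seed = seed)
  tibble::tibble(site_id = screens$site_id, cluster = ap$labels)
}

#' Cross-validated evaluation of residual clusters
#'
#' For every cluster with more than `min_size` sites, fits k-fold
#' cross-validated pacemaker and elastic-net models on the cluster's sites
#' and reports held-out age prediction error in years. Pacemaker states are
#' mapped to years with the square-root age trend fit on the training folds
#' ([fit_state_age_map()]). Also reports the trend \eqn{R^2} of the
#' full-cluster pacemaker states against the age trend.
#'
#' @param matrix Sites-by-samples beta matrix (training samples).
#' @param ages Per-sample ages.
#' @param labels Tibble from [cluster_residuals()].
#' @param min_size Only clusters with strictly more sites are evaluated.
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed (fold assignment).
#' @return A tibble with one row per evaluated cluster: `cluster_id`,
#'   `n_sites`, `site_ids` (list-column), `epm_cv_mae`, `enet_cv_mae`
#'   (years), `trend_r2`.
#' @export
evaluate_clusters <- function(matrix, ages, labels, min_size = 10, folds = 5,
                              seed = 1) {
  stopifnot(folds >= 2, ncol(matrix) == length(ages))
  n <- length(ages)
  if (n < 2 * folds) stop("too few samples for ", folds, "-fold evaluation", call. = FALSE)
  fold_id <- with_substream(substream_seed(seed, "cluster-folds"),
                            sample(rep_len(seq_len(folds), n)))
  sizes <- table(labels$cluster)
  eval_ids <- as.integer(names(sizes)[sizes > min_size])
  purrr::map_dfr(eval_ids, function(cl) {
    ids <- labels$site_id[labels$cluster == cl]
    if (length(ids) < 2) return(NULL)
    sub <- matrix[ids, , drop = FALSE]
    epm_err <- enet_err <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_epm(sub[, tr, drop = FALSE], ages[tr])
      map <- fit_state_age_map(fit$states, ages[tr])
      s_te <- predict_states(fit, sub[, !tr, drop = FALSE])
      epm_err[f] <- mean(abs(stats::predict(map, s_te) - ages[!tr]))
      clock <- fit_clock(sub[, tr, drop = FALSE], ages[tr],
                         seed = substream_seed(seed, "cluster-clock", cl, f))
      enet_err[f] <- mean(abs(predict_age(clock, sub[, !tr, drop = FALSE]) - ages[!tr]))
    }
    full <- fit_epm(sub, ages)
    trend <- stats::lm(full$states ~ ages + sqrt(ages))
    trend_r2 <- 1 - sum(stats::residuals(trend)^2) /
      sum((full$states - mean(full$states))^2)
    tibble::tibble(
      cluster_id = cl, n_sites = length(ids), site_ids = list(ids),
      epm_cv_mae = mean(epm_err), enet_cv_mae = mean(enet_err),
      trend_r2 = trend_r2
    )
  })
}

#' Merge well-performing clusters into a final site set
#'
#' Combines the sites of all clusters whose cross-validated pacemaker and
#' elastic-net errors are both below `mae_cutoff` years; the combined set is
#' used to fit the final models.
#'
#' @param reports Tibble from [evaluate_clusters()].
#' @param mae_cutoff MAE cutoff in years (default 6).
#' @return Character vector of site ids (union over passing clusters).
#' @export
merge_clusters <- function(reports, mae_cutoff = 6) {
  if (is.null(reports) || nrow(reports) == 0) {
    stop("no clusters were evaluated; nothing to merge (check cluster sizes ",
         "against `min_size`)", call. = FALSE)
  }
  pass <- reports$epm_cv_mae < mae_cutoff & reports$enet_cv_mae < mae_cutoff
  if (!any(pass)) {
    stop("no cluster has both EPM and elastic-net CV MAE below ", mae_cutoff,
         " years; relax `mae_cutoff` or revisit the upstream screens",
         call. = FALSE)
  }
  unique(unlist(reports$site_ids[pass]))
}
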