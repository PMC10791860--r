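#' Configuration for the simulation grid experiment
#'
#' Defaults reproduce the benchmark study design: a 5 x 5 grid crossing the
#' binary trait's on-exposure (`binary_q` from 0.995 to 1.0, five equally
#' spaced values) with the health standard deviation (0.0 to 0.01, five
#' equally spaced values), 50 replicates per cell, 500 samples per replicate,
#' 400 sites. The simulation-mode clock uses a fixed total penalty of 1 with
#' `l1_ratio = 0.75`.
#'
#' @param binary_q Vector of binary on-exposures.
#' @param health_sd Vector of health standard deviations.
#' @param reps Replicates per grid cell (>= 1).
#' @param n_samples Samples per replicate.
#' @param n_total_sites Total simulated sites (400 enumerated; 450 padded).
#' @param seed Top-level integer seed.
#' @param clock_penalty `"cv"` or a fixed total penalty (default 1).
#' @param year_mapped_states If `TRUE`, pacemaker states are converted to
#'   years via [fit_state_age_map()] before the moderation fit; by default
#'   raw states are used (the square-root age term absorbs the
#'   non-linearity).
#' @param out_dir Optional output directory for TSV results and the echoed
#'   config.
#' @return A named list (class `"grid_config"`).
#' @export
grid_config <- function(binary_q = seq(0.995, 1, length.out = 5),
                        health_sd = seq(0, 0.01, length.out = 5),
                        reps = 50, n_samples = 500, n_total_sites = 400,
                        seed = 1, clock_penalty = 1,
                        year_mapped_states = FALSE, out_dir = NULL) {
  stopifnot(reps >= 1, n_samples >= 8, all(binary_q >= 0.995 & binary_q <= 1),
            all(health_sd >= 0))
  structure(
    list(binary_q = binary_q, health_sd = health_sd, reps = reps,
         n_samples = n_samples, n_total_sites = n_total_sites, seed = seed,
         clock_penalty = clock_penalty,
         year_mapped_states = year_mapped_states, out_dir = out_dir),
    class = "grid_config"
  )
}

#' Simulate one grid cell and collect moderation p-values
#'
#' Runs `reps` independent replicates of one simulation condition: generate
#' the benchmark design at the given `binary_q` and `health_sd`, simulate a
#' cohort and methylation matrix, split the samples in half, fit the
#' pacemaker and the elastic-net clock on the training half, predict states
#' and ages for the test half, and fit the moderation regression
#' (outcome ~ age + sqrt(age) + health + binary) for both outcomes.
#'
#' @param binary_q Binary trait on-exposure for this cell.
#' @param health_sd Health standard deviation for this cell.
#' @param reps Number of replicates.
#' @param n_samples Samples per replicate.
#' @param seed Top-level seed; each replicate derives an independent
#'   sub-stream keyed by the cell condition and replicate index, so results
#'   do not depend on which other cells are run.
#' @param n_total_sites,clock_penalty,year_mapped_states See [grid_config()].
#' @return A tibble with one row per replicate, outcome and term:
#'   `binary_q`, `health_sd`, `rep`, `outcome` (`"epm_state"`/`"clock_age"`),
#'   `term`, `estimate`, `p.value`.
#' @export
run_grid_cell <- function(binary_q, health_sd, reps, n_samples = 500, seed = 1,
                          n_total_sites = 400, clock_penalty = 1,
                          year_mapped_states = FALSE) {
  purrr::map_dfr(seq_len(reps), function(r) {
    rs <- substream_seed(seed, "cell", round(binary_q * 1e6),
                         round(health_sd * 1e6), r)
    design <- benchmark_design(binary_q = binary_q, health_sd = health_sd,
                            seed = substream_seed(rs, "design"),
                            n_total_sites = n_total_sites)
    cohort <- simulate_cohort(n_samples, c(0, 100), health_sd = health_sd,
                              traits = design$traits,
                              seed = substream_seed(rs, "cohort"))
    mat <- simulate_methylation(cohort, design$sites,
                                seed = substream_seed(rs, "meth"))
    halves <- split_half(mat, cohort, seed = substream_seed(rs, "split"))
    tr <- halves$train
    te <- halves$test

    epm <- fit_epm(tr$matrix, tr$cohort$age)
    states_te <- predict_states(epm, te$matrix)
    if (year_mapped_states) {
      map <- fit_state_age_map(epm$states, tr$cohort$age)
      states_te <- stats::predict(map, states_te)
    }
    clock <- fit_clock(tr$matrix, tr$cohort$age, penalty = clock_penalty,
                       seed = substream_seed(rs, "clock"))
    ages_te <- predict_age(clock, te$matrix)

    design_te <- build_design(
      te$cohort$age,
      covariates = list(health = te$cohort$health, binary = te$cohort$on_bin1)
    )
    out <- dplyr::bind_rows(
      tidy.moderation_fit(fit_moderation(states_te, design_te, "epm_state")),
      tidy.moderation_fit(fit_moderation(ages_te, design_te, "clock_age"))
    )
    out$binary_q <- binary_q
    out$health_sd <- health_sd
    out$rep <- r
    out[, c("binary_q", "health_sd", "rep", "outcome", "term",
            "estimate", "p.value")]
  })
}

#' Run the full simulation grid experiment
#'
#' Crosses all `binary_q` and `health_sd` values in the configuration,
#' running [run_grid_cell()] for each cell, and summarizes the per-replicate
#' moderation p-values per cell, outcome and term (mean and standard
#' deviation). A cell that fails is logged, marked `NA` in the summary, and
#' the run continues.
#'
#' @param config A [grid_config()].
#' @return An object of class `"epm_sim_grid"`: a list with `per_rep` (tidy
#'   tibble of every replicate's moderation terms), `summary` (one row per
#'   cell, outcome and term with `mean_p` and `sd_p`) and `config`. If
#'   `config$out_dir` is set, `per_rep.tsv`, `summary.tsv` and `config.yaml`
#'   are written there.
#' @export
run_simulation_grid <- function(config = grid_config()) {
  cells <- tidyr::expand_grid(binary_q = config$binary_q,
                              health_sd = config$health_sd)
  per_rep <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    tryCatch(
      run_grid_cell(cell$binary_q, cell$health_sd, reps = config$reps,
                    n_samples = config$n_samples, seed = config$seed,
                    n_total_sites = config$n_total_sites,
                    clock_penalty = config$clock_penalty,
                    year_mapped_states = config$year_mapped_states),
      error = function(e) {
        message("grid cell (binary_q = ", cell$binary_q, ", health_sd = ",
                cell$health_sd, ") failed: ", conditionMessage(e))
        tibble::tibble(binary_q = cell$binary_q, health_sd = cell$health_sd,
                       rep = NA_integer_, outcome = NA_character_,
                       term = NA_character_, estimate = NA_real_,
                       p.value = NA_real_)
      }
    )
  })
  summary <- per_rep |>
    dplyr::filter(!is.na(.data$term)) |>
    dplyr::group_by(.data$binary_q, .data$health_sd, .data$outcome, .data$term) |>
    dplyr::summarise(
      mean_p = mean(.data$p.value), sd_p = stats::sd(.data$p.value),
      n_reps = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::right_join(
      tidyr::expand_grid(cells,
                         outcome = c("epm_state", "clock_age"),
                         term = c("binary", "health")),
      by = c("binary_q", "health_sd", "outcome", "term")
    ) |>
    dplyr::arrange(.data$binary_q, .data$health_sd, .data$outcome, .data$term)

  res <- structure(list(per_rep = per_rep, summary = summary, config = config),
                   class = "epm_sim_grid")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(per_rep, file.path(config$out_dir, "per_rep.tsv"))
    readr::write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
    write_config(unclass(config), file.path(config$out_dir, "config.yaml"))
  }
  res
}

#' @export
print.epm_sim_grid <- function(x, ...) {
  cat("Simulation grid:", length(x$config$binary_q), "x",
      length(x$config$health_sd), "cells,", x$config$reps, "reps,",
      x$config$n_samples, "samples/rep\n")
  print(x$summary, n = 20)
  invisible(x)
}

#' @method tidy epm_sim_grid
#' @export
tidy.epm_sim_grid <- function(x, ...) x$summary

#' Configuration for the build-and-moderate pipeline
#'
#' @param pcc_threshold Absolute age-correlation cutoff for [pcc_filter()].
#' @param mae_site Per-site MAE cutoff (beta units) for [mae_screen()].
#' @param mae_cluster Cluster MAE cutoff (years) for [merge_clusters()].
#' @param min_cluster_size Clusters with strictly more sites are evaluated.
#' @param variance_min Variance cutoff for the full elastic-net branch.
#' @param preference Affinity-propagation preference.
#' @param folds Cross-validation folds for cluster evaluation.
#' @param female_drop_threshold Female-proportion threshold for dropping the
#'   sex term.
#' @param clock_penalty `"cv"` or a fixed penalty for the final clocks.
#' @param full_clock Also fit the full variance-filtered elastic-net clock.
#' @param seed Top-level integer seed.
#' @param out_dir Optional output directory.
#' @return A named list (class `"pipeline_config"`).
#' @export
pipeline_config <- function(pcc_threshold = 0.4, mae_site = 0.025,
                            mae_cluster = 6, min_cluster_size = 10,
                            variance_min = 0.001, preference = -2.5,
                            folds = 5, female_drop_threshold = 0.7,
                            clock_penalty = "cv", full_clock = TRUE,
                            seed = 1, out_dir = NULL) {
  stopifnot(pcc_threshold > 0, mae_site > 0, mae_cluster > 0,
            variance_min > 0, folds >= 2)
  structure(
    list(pcc_threshold = pcc_threshold, mae_site = mae_site,
         mae_cluster = mae_cluster, min_cluster_size = min_cluster_size,
         variance_min = variance_min, preference = preference, folds = folds,
         female_drop_threshold = female_drop_threshold,
         clock_penalty = clock_penalty, full_clock = full_clock, seed = seed,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Build pacemaker and clock models and test for moderators
#'
#' The full model-building pipeline on a methylation matrix with per-sample
#' metadata: split samples in half; on the training half, screen sites by
#' absolute age correlation and by linear-in-age MAE, cluster the surviving
#' sites by the shape of their regression residuals (affinity propagation),
#' evaluate each sizeable cluster by cross-validated pacemaker and
#' elastic-net error, and merge the well-performing clusters into a final
#' site set; fit the final pacemaker and cluster clock on that set (plus,
#' optionally, the full variance-filtered clock); predict states and ages
#' for the held-out half; and fit the moderation regression of each outcome
#' on age, the square root of age, cell-type PCs (when fraction columns
#' `ct*` are present in `metadata`), any extra covariates, and sex.
#'
#' @param matrix Sites-by-samples beta matrix.
#' @param metadata Tibble with `sample_id` and `age` columns (matrix column
#'   order), optionally `sex`, cell-type fraction columns `ct1..ctK`, and
#'   extra covariate columns named in `covariate_cols`.
#' @param config A [pipeline_config()].
#' @param covariate_cols Optional character vector of extra metadata columns
#'   to enter the moderation model (e.g. an exposure measure).
#' @return An object of class `"epm_pipeline"`: list with `screens`,
#'   `clusters`, `cluster_reports`, `final_sites`, `epm`, `clock`
#'   (cluster-site clock), `full_clock` (or `NULL`), `age_map`, `metrics`
#'   (held-out R^2/MAE per model), `moderation` (tidy term table per
#'   outcome), `sex_dropped`, `config`.
#' @export
run_build_and_moderate <- function(matrix, metadata,
                                   config = pipeline_config(),
                                   covariate_cols = NULL) {
  stopifnot(ncol(matrix) == nrow(metadata), "age" %in% names(metadata))
  seed <- config$seed

  halves <- run_stage("split", split_half(matrix, metadata, seed = seed))
  tr <- halves$train
  te <- halves$test
  tr_age <- tr$cohort$age
  te_age <- te$cohort$age

  pcc <- run_stage("pcc_filter",
                   pcc_filter(tr$matrix, tr_age, config$pcc_threshold))
  message("  sites passing |PCC| > ", config$pcc_threshold, ": ", nrow(pcc))
  if (nrow(pcc) < 2) stop("pipeline stage `pcc_filter` retained < 2 sites", call. = FALSE)

  screens <- run_stage("mae_screen",
                       mae_screen(tr$matrix[pcc$site_id, , drop = FALSE],
                                  tr_age, config$mae_site))
  message("  sites passing MAE < ", config$mae_site, ": ", nrow(screens))
  if (nrow(screens) < 2) stop("pipeline stage `mae_screen` retained < 2 sites", call. = FALSE)

  clusters <- run_stage("cluster_residuals",
                        cluster_residuals(screens, preference = config$preference,
                                          seed = seed))
  reports <- run_stage("evaluate_clusters",
                       evaluate_clusters(tr$matrix, tr_age, clusters,
                                         min_size = config$min_cluster_size,
                                         folds = config$folds, seed = seed))
  final_sites <- run_stage("merge_clusters",
                           merge_clusters(reports, config$mae_cluster))
  message("  final site set: ", length(final_sites), " sites from ",
          sum(reports$epm_cv_mae < config$mae_cluster &
                reports$enet_cv_mae < config$mae_cluster), " cluster(s)")

  epm <- run_stage("fit_epm",
                   fit_epm(tr$matrix[final_sites, , drop = FALSE], tr_age))
  age_map <- fit_state_age_map(epm$states, tr_age)
  clock <- run_stage("fit_clock",
                     fit_clock(tr$matrix[final_sites, , drop = FALSE], tr_age,
                               seed = substream_seed(seed, "cluster-clock"),
                               penalty = config$clock_penalty))
  full_clock <- NULL
  if (isTRUE(config$full_clock)) {
    keep <- variance_filter(tr$matrix, config$variance_min)
    full_clock <- run_stage("fit_full_clock",
                            fit_clock(tr$matrix[keep, , drop = FALSE], tr_age,
                                      seed = substream_seed(seed, "full-clock"),
                                      penalty = config$clock_penalty))
  }

  states_te <- predict_states(epm, te$matrix)
  outcomes <- list(
    epm_state = states_te,
    clock_age = predict_age(clock, te$matrix)
  )
  if (!is.null(full_clock)) {
    outcomes$full_clock_age <- predict_age(full_clock, te$matrix)
  }
  metrics <- dplyr::bind_rows(
    dplyr::mutate(fit_metrics(te_age, stats::predict(age_map, states_te)),
                  model = "epm_state_years", .before = 1),
    purrr::map_dfr(setdiff(names(outcomes), "epm_state"), function(nm) {
      dplyr::mutate(fit_metrics(te_age, outcomes[[nm]]), model = nm, .before = 1)
    })
  )

  ct_cols <- grep("^ct[0-9]+$", names(metadata), value = TRUE)
  covariates <- list()
  if (length(ct_cols) >= 3) {
    pca <- fit_celltype_pca(as.matrix(tr$cohort[, ct_cols]))
    pcs <- stats::predict(pca, as.matrix(te$cohort[, ct_cols]))
    covariates <- c(covariates, as.list(as.data.frame(pcs)))
  }
  for (nm in covariate_cols %||% character()) {
    covariates[[nm]] <- te$cohort[[nm]]
  }
  design_te <- build_design(
    te_age, covariates = if (length(covariates)) covariates else NULL,
    sex_labels = te$cohort$sex,
    female_drop_threshold = config$female_drop_threshold
  )
  moderation <- run_stage("moderation", purrr::map_dfr(
    names(outcomes),
    function(nm) tidy.moderation_fit(fit_moderation(outcomes[[nm]], design_te, nm))
  ))

  res <- structure(
    list(screens = screens, clusters = clusters, cluster_reports = reports,
         final_sites = final_sites, epm = epm, clock = clock,
         full_clock = full_clock, age_map = age_map, metrics = metrics,
         moderation = moderation,
         sex_dropped = attr(design_te, "sex_dropped"), config = config),
    class = "epm_pipeline"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(moderation, file.path(config$out_dir, "moderation.tsv"))
    readr::write_tsv(metrics, file.path(config$out_dir, "metrics.tsv"))
    readr::write_tsv(tidy.epm(epm, "sites"),
                     file.path(config$out_dir, "epm_sites.tsv"))
    readr::write_tsv(tidy.epi_clock(clock),
                     file.path(config$out_dir, "clock_coefficients.tsv"))
    cfg <- unclass(config)
    write_config(cfg, file.path(config$out_dir, "config.yaml"))
  }
  res
}

#' @export
print.epm_pipeline <- function(x, ...) {
  cat("Build-and-moderate pipeline\n")
  cat("  screened sites:", nrow(x$screens),
      " final sites:", length(x$final_sites), "\n")
  cat("  held-out metrics:\n")
  print(x$metrics)
  invisible(x)
}

#' @method tidy epm_pipeline
#' @export
tidy.epm_pipeline <- function(x, ...) x$moderation

#' @method glance epm_pipeline
#' @export
glance.epm_pipeline <- function(x, ...) {
  tibble::tibble(
    n_screened = nrow(x$screens), n_clusters = max(x$clusters$cluster),
    n_final_sites = length(x$final_sites),
    sex_dropped = x$sex_dropped
  )
}
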