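#' Read and write beta-value matrices as TSV
#'
#' The on-disk dialect is a tab-separated table whose first column is
#' `site_id`, whose header row holds sample ids, and whose beta values are
#' written with 6 decimals. `read_matrix()` validates the file strictly:
#' ragged rows fail with the offending line number and values outside
#' `[0, 1]` fail with the site/sample coordinates of the first bad cell.
#'
#' @param path File path.
#' @param matrix Sites-by-samples beta matrix with dimnames.
#' @return `read_matrix()` returns the numeric matrix (sites in rows);
#'   `write_matrix()` returns `path` invisibly.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    stop("`", path, "` does not contain a header and at least one site row",
         call. = FALSE)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  n_col <- length(header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1]
    stop("ragged row at line ", bad + 1L, ": expected ", n_col, " fields, got ",
         widths[bad], call. = FALSE)
  }
  site_ids <- vapply(rows, `[[`, character(1), 1)
  values <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(rows, `[`, -1)))),
    nrow = length(rows), ncol = n_col - 1L, byrow = TRUE,
    dimnames = list(site_ids, sample_ids)
  )
  bad <- which(!is.finite(values) | values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("beta value out of [0, 1] (or non-numeric) at site ",
         site_ids[bad[1, 1]], ", sample ", sample_ids[bad[1, 2]], call. = FALSE)
  }
  values
}

#' @rdname read_matrix
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(!is.null(rownames(matrix)), !is.null(colnames(matrix)))
  header <- paste(c("site_id", colnames(matrix)), collapse = "\t")
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], sprintf("%.6f", matrix[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write cohort metadata as TSV
#'
#' @param cohort Cohort tibble (e.g. from [simulate_cohort()], optionally
#'   with cell-type fraction columns bound on).
#' @param path File path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns `path`
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and write run configuration as YAML
#'
#' @param config A configuration list ([grid_config()] or
#'   [pipeline_config()]).
#' @param path File path.
#' @return `read_config()` returns the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Reference-anchored quantile normalization by probe type
#'
#' Builds a reference distribution from the per-site medians of a training
#' matrix, separately within each probe-type stratum, and maps each sample's
#' values onto that reference by rank (within the same stratum). With a
#' single stratum this is ordinary reference-based quantile normalization;
#' with `probe_types` it mirrors array-style normalization stratified by
#' probe chemistry. For simulated data (no probe-type structure) it is a
#' no-op unless explicitly applied.
#'
#' @param matrix_train Training beta matrix (sites x samples) used to build
#'   the reference.
#' @param probe_types Optional character/factor vector, one entry per site,
#'   naming each site's stratum; `NULL` puts all sites in one stratum.
#' @return `qn_reference()` returns an object of class `"qn_reference"`;
#'   `quantile_normalize(matrix, reference)` returns the normalized matrix.
#' @export
qn_reference <- function(matrix_train, probe_types = NULL) {
  n_site <- nrow(matrix_train)
  probe_types <- probe_types %||% rep("all", n_site)
  stopifnot(length(probe_types) == n_site)
  med <- apply(matrix_train, 1, stats::median)
  ref <- lapply(split(med, probe_types), sort)
  structure(list(reference = ref, probe_types = probe_types),
            class = "qn_reference")
}

#' @rdname qn_reference
#' @param matrix Beta matrix to normalize (same sites, same order, as the
#'   training matrix).
#' @param reference A `"qn_reference"` object.
#' @export
quantile_normalize <- function(matrix, reference) {
  stopifnot(inherits(reference, "qn_reference"),
            nrow(matrix) == length(reference$probe_types))
  out <- matrix
  for (type in names(reference$reference)) {
    idx <- which(reference$probe_types == type)
    ref <- reference$reference[[type]]
    for (j in seq_len(ncol(matrix))) {
      v <- matrix[idx, j]
      rk <- rank(v, ties.method = "average")
      # interpolate the reference quantiles at the sample's rank positions
      out[idx, j] <- stats::quantile(ref, probs = (rk - 1) / (length(v) - 1),
                                     type = 7, names = FALSE)
    }
  }
  out
}
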