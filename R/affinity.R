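#' Affinity-propagation clustering
#'
#' Exemplar-based clustering by message passing on a pairwise similarity
#' matrix (Frey-Dueck responsibility/availability updates). The `preference`
#' (the self-similarity placed on the diagonal) governs how many exemplars
#' emerge: lower preferences give fewer clusters. A tiny seeded jitter is
#' added to the similarities to break ties deterministically, and updates are
#' damped for stability on near-duplicate inputs.
#'
#' @param s Square similarity matrix (larger = more similar); typically a
#'   negative squared Euclidean distance.
#' @param preference Diagonal self-similarity (scalar or per-point vector).
#' @param damping Damping factor in `[0.5, 1)`.
#' @param max_iter Maximum number of message-passing iterations.
#' @param convergence_iter Number of consecutive iterations with unchanged
#'   exemplars required to declare convergence.
#' @param seed Integer seed for the tie-breaking jitter.
#' @return A list with `labels` (integer cluster label per point, `1..K`),
#'   `exemplars` (indices), `converged`, `n_iter`. If the messages do not
#'   converge, a warning is raised and every point is labeled a singleton.
#' @export
affinity_propagation <- function(s, preference = stats::median(s[upper.tri(s) | lower.tri(s)]),
                                 damping = 0.9, max_iter = 1000,
                                 convergence_iter = 15, seed = 1) {
  s <- as.matrix(s)
  n <- nrow(s)
  stopifnot(n == ncol(s), n >= 2, damping >= 0.5, damping < 1)
  diag(s) <- preference
  # deterministic tie-breaking jitter, scaled far below the data
  eps <- .Machine$double.eps
  tiny <- .Machine$double.xmin * 100
  noise <- with_substream(substream_seed(seed, "ap-jitter"),
                          matrix(stats::rnorm(n * n), n, n))
  s <- s + (eps * s + tiny) * noise

  r <- matrix(0, n, n)
  a <- matrix(0, n, n)
  e_hist <- matrix(FALSE, n, convergence_iter)
  idx <- seq_len(n)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    # responsibilities
    tmp <- a + s
    i_max <- max.col(tmp, ties.method = "first")
    y <- tmp[cbind(idx, i_max)]
    tmp[cbind(idx, i_max)] <- -Inf
    y2 <- tmp[cbind(idx, max.col(tmp, ties.method = "first"))]
    rn <- s - y
    rn[cbind(idx, i_max)] <- s[cbind(idx, i_max)] - y2
    r <- damping * r + (1 - damping) * rn
    # availabilities
    rp <- pmax(r, 0)
    diag(rp) <- diag(r)
    cs <- colSums(rp)
    an <- sweep(-rp, 2, cs, "+")  # colsum_k - rp[i,k]
    da <- diag(an)                # = sum_{i' != k} max(0, r(i',k))
    an <- pmin(an, 0)
    diag(an) <- da
    a <- damping * a + (1 - damping) * an

    e <- (diag(a) + diag(r)) > 0
    e_hist[, (it - 1) %% convergence_iter + 1] <- e
    if (it >= convergence_iter) {
      se <- rowSums(e_hist)
      stable <- all(se == 0 | se == convergence_iter)
      if (stable && any(e)) {
        converged <- TRUE
        break
      }
    }
  }

  exemplars <- which((diag(a) + diag(r)) > 0)
  if (!converged || length(exemplars) == 0) {
    warning("affinity propagation did not converge; labeling all points as singletons",
            call. = FALSE)
    return(list(labels = seq_len(n), exemplars = seq_len(n),
                converged = FALSE, n_iter = it))
  }
  k <- length(exemplars)
  cl <- max.col(s[, exemplars, drop = FALSE], ties.method = "first")
  cl[exemplars] <- seq_len(k)
  # refine each exemplar to the member maximizing within-cluster similarity
  for (j in seq_len(k)) {
    members <- which(cl == j)
    if (length(members) > 1) {
      within <- colSums(s[members, members, drop = FALSE])
      exemplars[j] <- members[which.max(within)]
    }
  }
  cl <- max.col(s[, exemplars, drop = FALSE], ties.method = "first")
  cl[exemplars] <- seq_len(k)
  list(labels = cl, exemplars = exemplars, converged = TRUE, n_iter = it)
}
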