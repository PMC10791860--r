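#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one top-level integer seed.
#' Components (traits, sites, folds, replicates) draw from sub-streams whose
#' seeds are derived deterministically from the top-level seed and a path of
#' identifiers, so that e.g. adding sites to a design does not perturb the
#' draws of earlier sites.
#'
#' @param seed Top-level integer seed.
#' @param ... Path of identifiers (integers or strings) naming the sub-stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "ages")
#' substream_seed(1, "site", 12)
substream_seed <- function(seed, ...) {
  parts <- list(...)
  x <- (abs(as.double(seed)) %% 2147483647)
  step <- function(x, k) {
    # 48271 is the MINSTD multiplier; doubles stay < 2^53 so arithmetic is exact
    ((x + k + 1) * 48271) %% 2147483647
  }
  for (p in parts) {
    if (is.character(p)) {
      for (ch in utf8ToInt(p)) x <- step(x, ch)
    } else {
      x <- step(x, as.double(p) %% 2147483647)
    }
  }
  as.integer(x %% 2147483645 + 1)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# state is untouched.
with_substream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
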