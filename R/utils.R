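# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are deterministic given
#' their `seed` argument without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

#' Type-7 (linear interpolation) quantile, the convention used throughout
#' for clipping percentiles, positivity thresholds and decile cut points.
#' @noRd
quantile7 <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = TRUE))
}

#' Age-group vocabulary, ordered young -> old.
#' @noRd
age_groups <- function() c("young", "middle", "old")

#' Anatomical annotation region vocabulary: cortical layers then white matter.
#' @noRd
aar_levels <- function() c("L1", "L2", "L3", "L4", "L5", "L6", "WM")

#' Representative donor ages used when only the group is known
#' (young <45, middle 45-55, old >55).
#' @noRd
age_group_midpoints <- function() c(young = 35, middle = 50, old = 70)

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
}

#' Depth-normalise counts to a target (default 10k) and log1p-transform.
#' Rows are cells/spots, columns genes. Returns a dense matrix.
#' @noRd
normalize_log1p <- function(counts, target = 1e4) {
  depth <- Matrix::rowSums(counts)
  depth[depth == 0] <- 1
  m <- as.matrix(counts / depth * target)
  log1p(m)
}
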