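#' Maximum-likelihood estimates of zero-inflated Poisson parameters
#'
#' Fits `y ~ ZIP(lambda, theta)` by maximising the likelihood over
#' `(log lambda, logit theta)`. All-zero input has no identified `lambda`;
#' it is returned as `NA` with `theta = 1` and a flag. Samples with no
#' zeros drive `theta` to the 0 boundary.
#'
#' @param counts Non-negative integer counts, `n >= 2`.
#' @return Tibble `lambda`, `theta`, `loglik`, `all_zero`.
#' @export
mle_zip <- function(counts) {
  if (length(counts) < 2) abort("need at least 2 observations")
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers")
  }
  if (all(counts == 0)) {
    return(tibble(lambda = NA_real_, theta = 1, loglik = 0, all_zero = TRUE))
  }
  n0 <- sum(counts == 0)
  pos <- counts[counts > 0]
  nll <- function(par) {
    lam <- exp(par[1])
    th <- stats::plogis(par[2])
    -(n0 * log(th + (1 - th) * exp(-lam)) +
        (length(pos)) * log(1 - th) +
        sum(stats::dpois(pos, lam, log = TRUE)))
  }
  init <- c(log(mean(counts) + 0.01), stats::qlogis(max(min(
    n0 / length(counts), 0.95), 0.05)))
  opt <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  tibble(lambda = exp(opt$par[1]),
         theta = stats::plogis(opt$par[2]),
         loglik = -opt$value, all_zero = FALSE)
}

#' Expression levels used by the simulation power study
#'
#' LOW = 0.025, MEDIUM = 0.6, HIGH = 10 mean counts/spot, spanning the 20th,
#' 90th and 99.9th percentiles of real cortical spatial expression.
#' @return Named numeric vector.
#' @export
power_levels <- function() c(LOW = 0.025, MEDIUM = 0.6, HIGH = 10)

#' Simulation power study for the Bayes-factor spatial DE test
#'
#' Per replicate, simulates a control and a comparison group of square
#' arrays at the chosen expression level (the comparison group's rate is
#' multiplied by `fold_change`), fits the ZIP spatial model (variational
#' backend by default), and computes the Savage-Dickey Bayes factor of the
#' group difference per AAR and pooled over AARs ("overall", the mean of
#' the per-AAR differences). Detection requires `BF > bf_threshold` and
#' the correct sign. Power is the fraction of replicates detected;
#' replicates whose fit fails to converge are excluded from the
#' denominator (with a log).
#'
#' The stated level is the ZIP mean counts/spot, so the Poisson rate is
#' `level / (1 - theta)`.
#'
#' @param level `"LOW"`, `"MEDIUM"` or `"HIGH"` (or a numeric mean
#'   counts/spot).
#' @param fold_change Simulated fold change (1 = null).
#' @param n_arrays_per_group Arrays per group (default 20).
#' @param n_reps Replicates (>= 20 for a stable estimate).
#' @param grid_shape Array grid (default 15 x 15 across the 7 AAR bands).
#' @param theta Zero-inflation probability (default 0.1).
#' @param backend Model backend (default `"vi"`; `"mcmc"` for audit runs).
#' @param draws Posterior draws per fit.
#' @param bf_threshold Detection threshold (default 3).
#' @param seed Integer seed.
#' @return A `power_result` tibble: rows per AAR plus `"overall"`, with
#'   `power`, Wilson 95% CI, `n_detected`, `n_used`, and the design as
#'   columns.
#' @export
estimate_power <- function(level = "MEDIUM", fold_change = 1.2,
                           n_arrays_per_group = 20, n_reps = 50,
                           grid_shape = c(15, 15), theta = 0.1,
                           backend = "vi", draws = 800,
                           bf_threshold = 3, seed = 1L) {
  lam0 <- if (is.character(level)) power_levels()[[level]] else level
  level_lab <- if (is.character(level)) level else sprintf("%g", level)
  if (n_reps < 20) abort("`n_reps` must be >= 20")
  b0 <- log(lam0 / (1 - theta))
  aars <- aar_levels()
  det <- matrix(0L, n_reps, length(aars) + 1,
                dimnames = list(NULL, c(aars, "overall")))
  used <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- (seed * 10007L + r) %% .Machine$integer.max
    beta_table <- array(b0, dim = c(1, 7, 2),
                        dimnames = list(NULL, aars, c("young", "old")))
    beta_table[1, , "old"] <- b0 + log(fold_change)
    cfg <- sim_config(
      n_donors_per_group = c(young = n_arrays_per_group,
                             old = n_arrays_per_group),
      arrays_per_donor = 1, grid_shape = grid_shape, n_genes = 1,
      theta = theta, beta_table = beta_table,
      spatial_sd = 0, noise_sd = 0,
      frac_mito = 0, frac_lnc = 0, frac_pseudo = 0,
      seed = rep_seed
    )
    ds <- generate_spatial_dataset(cfg)$dataset
    fit <- tryCatch(
      fit_gene_model(ds, gene = colnames(ds$counts)[1], backend = backend,
                     draws = draws, seed = rep_seed),
      warning = function(w) NULL, error = function(e) NULL
    )
    if (is.null(fit)) {
      inform(sprintf("estimate_power: replicate %d flagged/non-converged, excluded", r))
      next
    }
    used[r] <- TRUE
    psd <- sqrt(2) * fit$sigma_beta
    deltas <- fit$beta_draws[, , "old"] - fit$beta_draws[, , "young"]
    for (a in seq_along(aars)) {
      bf <- savage_dickey_bf(deltas[, a], psd)
      det[r, a] <- as.integer(bf > bf_threshold &&
                                sign(mean(deltas[, a])) ==
                                  sign(log(fold_change) + 1e-12))
    }
    overall <- rowMeans(deltas)
    bf <- savage_dickey_bf(overall, psd / sqrt(length(aars)))
    det[r, "overall"] <- as.integer(bf > bf_threshold &&
                                      sign(mean(overall)) ==
                                        sign(log(fold_change) + 1e-12))
  }
  n_used <- sum(used)
  if (n_used == 0) abort("all replicates failed")
  out <- purrr::map(colnames(det), function(a) {
    k <- sum(det[used, a])
    ci <- wilson_ci(k, n_used)
    tibble(level = level_lab, fold_change = fold_change,
           n_arrays = n_arrays_per_group, aar = a,
           power = k / n_used, ci_lo = ci[1], ci_hi = ci[2],
           n_detected = k, n_used = n_used)
  }) |> bind_rows()
  class(out) <- c("power_result", class(out))
  out
}

wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}
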