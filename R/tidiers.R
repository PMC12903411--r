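#' Tidy a fitted ZIP spatial model
#'
#' One row per (AAR, age group) with the posterior mean, sd and credible
#' interval of the characteristic log expression rate `beta`.
#'
#' @param x A `zip_spatial_fit`.
#' @param conf_level Credible-interval mass (default 0.90).
#' @param ... Unused.
#' @return Tibble `aar`, `group`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.zip_spatial_fit <- function(x, conf_level = 0.90, ...) {
  a <- (1 - conf_level) / 2
  purrr::map(x$groups, function(g) {
    dr <- x$beta_draws[, , g, drop = FALSE]
    tibble(
      aar = x$aars, group = g,
      estimate = apply(dr, 2, mean),
      std.error = apply(dr, 2, sd),
      conf.low = apply(dr, 2, quantile7, a),
      conf.high = apply(dr, 2, quantile7, 1 - a)
    )
  }) |> bind_rows()
}

#' Glance at a fitted ZIP spatial model
#'
#' @param x A `zip_spatial_fit`.
#' @param ... Unused.
#' @return One-row tibble: `gene`, `backend`, `theta`, `tau`, `sigma`,
#'   `n_draws`, `max_rhat`, `converged`.
#' @export
glance.zip_spatial_fit <- function(x, ...) {
  tibble(
    gene = x$gene, backend = x$backend,
    theta = mean(x$theta_draws),
    tau = mean(x$tau_draws),
    sigma = mean(x$sigma_draws),
    n_draws = length(x$theta_draws),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' Tidy a transcript-positivity trend
#'
#' @param x A `positivity_trend` from [cdkn2a_positivity()].
#' @param ... Unused.
#' @return The per-donor tibble with `donor_id`, `age`, `n`,
#'   `pct_positive`.
#' @export
tidy.positivity_trend <- function(x, ...) x$per_donor

#' Glance at a transcript-positivity trend
#'
#' @param x A `positivity_trend`.
#' @param ... Unused.
#' @return One-row tibble: `gene`, `cell_class`, `slope`, `p`, `r2`,
#'   `n_donors`.
#' @export
glance.positivity_trend <- function(x, ...) {
  tibble(gene = x$gene, cell_class = x$cell_class, slope = x$slope,
         p = x$p, r2 = x$r2, n_donors = nrow(x$per_donor))
}
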