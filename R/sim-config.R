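#' Simulation configuration for synthetic spatial and single-nucleus data
#'
#' Defines the study conditions emulated by the synthetic-data generators:
#' a cohort of donors split into young / middle / old age groups, each donor
#' contributing one or more square spatial arrays whose rows are partitioned
#' into seven horizontal anatomical annotation region (AAR) bands (cortical
#' layers L1-L6 and the white matter), plus a matched single-nucleus dataset
#' with broad cell classes and optional planted senescent subpopulations.
#'
#' Spatial counts follow a zero-inflated Poisson (ZIP): a spot's count for a
#' gene is a structural zero with probability `theta`, otherwise
#' Poisson(lambda) with
#' `log lambda = beta[gene, aar, group] + psi + eps`, where `psi` is a
#' spatially autocorrelated field on the array grid (scale `spatial_sd`) and
#' `eps` iid spot noise (scale `noise_sd`). `beta_table` is on the natural-log
#' scale (log counts/spot).
#'
#' @param n_donors_per_group Named integer vector, donors per age group
#'   (`young`, `middle`, `old`). Groups with 0 donors are omitted.
#' @param arrays_per_donor Arrays (tissue sections) per donor.
#' @param grid_shape Integer `(rows, cols)` of each array's spot grid.
#' @param n_genes Number of genes.
#' @param aar_band_rows Named integer vector of band heights (rows) for the
#'   AARs, in order L1..L6, WM; must sum to `grid_shape[1]`. Defaults to a
#'   near-equal split.
#' @param theta Zero-inflation probability in `[0, 1]`.
#' @param beta_table Optional `gene x AAR x group` array of natural-log rates.
#'   Defaults to `baseline_log_rate` everywhere, then any `planted_modules`
#'   effects are added.
#' @param baseline_log_rate Baseline natural-log counts/spot.
#' @param spatial_sd Scale of the spatial autocorrelation field (>= 0).
#' @param noise_sd Scale of iid spot noise (>= 0).
#' @param planted_modules List of planted coexpression programs; each element
#'   is a list with `genes` (integer indices), `aar_effect` (named numeric,
#'   log-rate offsets by AAR; unnamed scalar recycles to all AARs) and
#'   `group_effect` (named numeric, log-rate offsets by age group). Effects
#'   are added to `beta_table`.
#' @param frac_mito,frac_lnc,frac_pseudo Fractions of genes flagged as
#'   mitochondrial / lncRNA / pseudogene in the gene metadata.
#' @param n_nuclei_per_donor Nuclei per donor in the matched snRNA-seq data.
#' @param cell_types Character vector of broad cell classes.
#' @param cell_type_props Either a single named numeric vector of class
#'   proportions (recycled across groups) or a `group x cell type` matrix.
#' @param n_markers_per_type Marker genes carved per cell class.
#' @param marker_boost Fold increase of a marker gene's rate in its class.
#' @param nuclei_depth Mean UMI depth per nucleus.
#' @param planted_senescence List describing the planted senescent
#'   subpopulation: `cell_type`, `fraction` (named per age group), `genes`
#'   (indices of over-expressed hallmark genes) and `effect` (fold change,
#'   e.g. 2 for 2x over-expression).
#' @param seed Integer seed; all generators are byte-identical given it.
#'
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(n_donors_per_group = c(young = 4, middle = 4, old = 4),
                       arrays_per_donor = 1,
                       grid_shape = c(12, 12),
                       n_genes = 120,
                       aar_band_rows = NULL,
                       theta = 0.1,
                       beta_table = NULL,
                       baseline_log_rate = log(0.6),
                       spatial_sd = 0.3,
                       noise_sd = 0.2,
                       planted_modules = list(),
                       frac_mito = 0.02,
                       frac_lnc = 0.02,
                       frac_pseudo = 0.02,
                       n_nuclei_per_donor = 150,
                       cell_types = c("Ast", "End", "Exc", "Inh",
                                      "Mic", "Oli", "OPC", "Peri"),
                       cell_type_props = NULL,
                       n_markers_per_type = 5,
                       marker_boost = 8,
                       nuclei_depth = 2000,
                       planted_senescence = NULL,
                       seed = 1L) {
  groups <- names(n_donors_per_group)
  if (is.null(groups)) {
    names(n_donors_per_group) <- age_groups()[seq_along(n_donors_per_group)]
    groups <- names(n_donors_per_group)
  }
  if (!all(groups %in% age_groups())) {
    abort("`n_donors_per_group` names must be among young/middle/old.")
  }
  n_donors_per_group <- n_donors_per_group[n_donors_per_group > 0]
  if (length(n_donors_per_group) < 1) abort("need at least one age group")

  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape < 1) ||
      prod(grid_shape) < 2) {
    abort("`grid_shape` must give a grid with at least 2 spots.")
  }
  if (is.null(aar_band_rows)) {
    aar_band_rows <- default_bands(grid_shape[1])
  }
  if (is.null(names(aar_band_rows))) names(aar_band_rows) <- aar_levels()
  if (!identical(sort(names(aar_band_rows)), sort(aar_levels()))) {
    abort("`aar_band_rows` must be named with the seven AARs L1..L6, WM.")
  }
  aar_band_rows <- aar_band_rows[aar_levels()]
  if (sum(aar_band_rows) != grid_shape[1] || any(aar_band_rows < 0)) {
    abort("`aar_band_rows` must cover all grid rows exactly once.")
  }
  stopifnot_scalar_prob(theta, "theta")
  if (spatial_sd < 0 || noise_sd < 0) abort("effect scales must be >= 0")
  if (n_genes < 1) abort("`n_genes` must be >= 1")

  if (is.null(beta_table)) {
    beta_table <- array(
      baseline_log_rate,
      dim = c(n_genes, length(aar_levels()), length(names(n_donors_per_group))),
      dimnames = list(NULL, aar_levels(), names(n_donors_per_group))
    )
  }
  if (!all(is.finite(beta_table))) abort("`beta_table` must be finite.")
  if (dim(beta_table)[1] != n_genes) {
    abort("`beta_table` gene dimension must equal `n_genes`.")
  }

  # fold planted module programs into the beta table
  for (pm in planted_modules) {
    g <- pm$genes
    ae <- pm$aar_effect %||% 0
    if (is.null(names(ae))) ae <- setNames(rep(ae[1], 7), aar_levels())
    ge <- pm$group_effect %||% 0
    if (is.null(names(ge))) {
      ge <- setNames(rep(ge[1], dim(beta_table)[3]), dimnames(beta_table)[[3]])
    }
    for (a in aar_levels()) {
      for (grp in dimnames(beta_table)[[3]]) {
        beta_table[g, a, grp] <- beta_table[g, a, grp] +
          (ae[a] %||% 0) + (ge[grp] %||% 0)
      }
    }
  }

  if (!is.null(planted_senescence)) {
    fr <- planted_senescence$fraction
    if (any(fr < 0 | fr > 1)) abort("senescent fractions must lie in [0, 1].")
    if (!planted_senescence$cell_type %in% cell_types) {
      abort("planted senescent cell type not among `cell_types`.")
    }
  }

  if (is.null(cell_type_props)) {
    cell_type_props <- setNames(rep(1 / length(cell_types), length(cell_types)),
                                cell_types)
  }

  structure(
    list(
      n_donors_per_group = n_donors_per_group,
      arrays_per_donor = as.integer(arrays_per_donor),
      grid_shape = grid_shape,
      n_genes = as.integer(n_genes),
      aar_band_rows = aar_band_rows,
      theta = theta,
      beta_table = beta_table,
      spatial_sd = spatial_sd,
      noise_sd = noise_sd,
      planted_modules = planted_modules,
      frac_mito = frac_mito,
      frac_lnc = frac_lnc,
      frac_pseudo = frac_pseudo,
      n_nuclei_per_donor = as.integer(n_nuclei_per_donor),
      cell_types = cell_types,
      cell_type_props = cell_type_props,
      n_markers_per_type = as.integer(n_markers_per_type),
      marker_boost = marker_boost,
      nuclei_depth = nuclei_depth,
      planted_senescence = planted_senescence,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# near-equal split of grid rows into the seven AAR bands
default_bands <- function(nrows) {
  base <- nrows %/% 7
  extra <- nrows %% 7
  widths <- rep(base, 7)
  if (extra > 0) widths[7] <- widths[7] + extra  # white matter takes the rest
  if (any(widths < 1) && nrows >= 7) widths <- rep(1, 7)
  setNames(widths, aar_levels())
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  donors/group:",
      paste(names(x$n_donors_per_group), x$n_donors_per_group,
            sep = "=", collapse = ", "), "\n")
  cat("  arrays/donor:", x$arrays_per_donor,
      " grid:", paste(x$grid_shape, collapse = "x"),
      " genes:", x$n_genes, "\n")
  cat("  theta:", x$theta, " spatial_sd:", x$spatial_sd,
      " noise_sd:", x$noise_sd, "\n")
  invisible(x)
}
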