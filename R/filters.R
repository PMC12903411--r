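#' Filter genes by biotype flags and spot detection fraction
#'
#' Removes genes flagged mitochondrial / lncRNA / pseudogene, and genes
#' detected (count > 0) in fewer than `min_spot_fraction` of spots. The
#' default 0.67% detection floor corresponds to the expression level of
#' *CDKN2A*, the least-expressed gene of interest. Surviving gene order is
#' preserved; per-criterion removal counts are attached as the
#' `"filter_log"` attribute and reported via [message()].
#'
#' @param ds A `spatial_dataset` with biotype flags in `gene_meta`.
#' @param min_spot_fraction Minimum fraction of spots with a nonzero count.
#' @return The filtered `spatial_dataset`.
#' @export
filter_genes <- function(ds, min_spot_fraction = 0.0067) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (is.null(ds$gene_meta$biotype)) abort("gene biotype flags are required")
  flagged <- ds$gene_meta$biotype %in% c("mito", "lncRNA", "pseudogene")
  det <- Matrix::colSums(ds$counts > 0) / nrow(ds$counts)
  low <- det < min_spot_fraction
  keep <- !flagged & !low
  log <- c(n_flagged_biotype = sum(flagged),
           n_below_detection = sum(low & !flagged),
           n_kept = sum(keep))
  if (!any(keep)) {
    abort(sprintf(
      "no genes survive: %d removed by biotype flags, %d below the %.2f%% detection floor",
      sum(flagged), sum(low & !flagged), 100 * min_spot_fraction))
  }
  out <- subset_spatial(ds, genes = which(keep))
  inform(sprintf("filter_genes: removed %d flagged + %d low-detection genes; %d kept",
                 log[1], log[2], log[3]))
  attr(out, "filter_log") <- log
  out
}

#' Filter spots by UMI depth, annotation validity and spatial connectivity
#'
#' Keeps spots with UMI depth (over the current gene set) at least
#' `min_umi`, a valid AAR label, and at least one surviving grid neighbour
#' within the same array. Neighbour pruning iterates to a fixpoint: removing
#' a spot can isolate its neighbours, which are then removed in turn. Run
#' after [filter_genes()] so UMI sums reflect the retained genes.
#'
#' @param ds A `spatial_dataset`.
#' @param min_umi Minimum UMI count (inclusive: spots with exactly
#'   `min_umi` are kept).
#' @return The filtered `spatial_dataset`, with removal counts in the
#'   `"filter_log"` attribute.
#' @export
filter_spots <- function(ds, min_umi = 100) {
  stopifnot(inherits(ds, "spatial_dataset"))
  umi <- Matrix::rowSums(ds$counts)
  valid_aar <- ds$spot_meta$aar %in% aar_levels()
  keep <- umi >= min_umi & valid_aar
  n_umi_fail <- sum(umi < min_umi)
  n_aar_fail <- sum(!valid_aar & umi >= min_umi)

  # iterate neighbour pruning until stable
  n_isolated <- 0L
  repeat {
    idx <- which(keep)
    if (length(idx) == 0) break
    key <- paste(ds$spot_meta$array_id, ds$spot_meta$row, ds$spot_meta$col)
    alive <- key[idx]
    has_nbr <- vapply(idx, function(s) {
      r <- ds$spot_meta$row[s]; cl <- ds$spot_meta$col[s]
      a <- ds$spot_meta$array_id[s]
      any(paste(a, c(r - 1, r + 1, r, r), c(cl, cl, cl - 1, cl + 1)) %in% alive)
    }, logical(1))
    if (all(has_nbr)) break
    keep[idx[!has_nbr]] <- FALSE
    n_isolated <- n_isolated + sum(!has_nbr)
  }
  if (!any(keep)) abort("no spots survive filtering")
  out <- subset_spatial(ds, spots = which(keep))
  log <- c(n_low_umi = n_umi_fail, n_invalid_aar = n_aar_fail,
           n_isolated = n_isolated, n_kept = sum(keep))
  inform(sprintf(
    "filter_spots: removed %d low-UMI, %d unannotated, %d isolated spots; %d kept",
    log[1], log[2], log[3], log[4]))
  attr(out, "filter_log") <- log
  out
}

#' Quality-control nuclei and strip mitochondrial genes
#'
#' Retains nuclei with UMI depth strictly greater than `min_umi` and a
#' mitochondrial fraction strictly below `max_mt`, then removes
#' mitochondrial genes from the matrix and refreshes the per-nucleus
#' `n_umi` / `mt_frac` columns so they describe the returned matrix.
#'
#' @param ds A `nuclei_dataset` with mitochondrial flags in `gene_meta`.
#' @param min_umi Strict lower UMI bound (a nucleus at exactly `min_umi`
#'   is removed).
#' @param max_mt Strict upper mitochondrial-fraction bound.
#' @return The filtered `nuclei_dataset`.
#' @export
qc_nuclei <- function(ds, min_umi = 500, max_mt = 0.05) {
  stopifnot(inherits(ds, "nuclei_dataset"))
  if (is.null(ds$gene_meta$biotype)) abort("gene biotype flags are required")
  umi <- Matrix::rowSums(ds$counts)
  mt_cols <- which(ds$gene_meta$biotype == "mito")
  mt_frac <- if (length(mt_cols)) {
    Matrix::rowSums(ds$counts[, mt_cols, drop = FALSE]) / pmax(umi, 1)
  } else rep(0, nrow(ds$counts))
  keep <- umi > min_umi & mt_frac < max_mt
  if (!any(keep)) abort("no nuclei survive QC")
  out <- subset_nuclei(ds, nuclei = which(keep))
  if (length(mt_cols)) {
    out <- subset_nuclei(out, genes = which(out$gene_meta$biotype != "mito"))
  }
  out$nuc_meta$n_umi <- as.integer(Matrix::rowSums(out$counts))
  out$nuc_meta$mt_frac <- 0
  log <- c(n_low_umi = sum(umi <= min_umi),
           n_high_mt = sum(mt_frac >= max_mt & umi > min_umi),
           n_kept = sum(keep))
  inform(sprintf("qc_nuclei: removed %d low-UMI, %d high-MT nuclei; %d kept",
                 log[1], log[2], log[3]))
  attr(out, "filter_log") <- log
  out
}
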