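#' Pseudobulk nuclei per (cell type, donor)
#'
#' Sums counts per (broad class, donor) pseudo-sample, drops cell types
#' lacking at least `min_cells` nuclei in at least `min_donors` donors,
#' then depth-normalises each pseudo-sample to `1e4` counts and
#' log1p-transforms.
#'
#' @param nuclei A QC'd `nuclei_dataset`.
#' @param min_cells,min_donors Cell-type retention rule (default 10 cells
#'   in 2 donors).
#' @return A `pseudobulk` object: `mat` (pseudo-sample x gene, normalised),
#'   `raw` (summed counts), `meta` tibble (`cell_type`, `donor_id`, `n_cells`
#'   and donor covariates).
#' @export
pseudobulk_nuclei <- function(nuclei, min_cells = 10, min_donors = 2) {
  stopifnot(inherits(nuclei, "nuclei_dataset"))
  meta <- nuclei$nuc_meta
  key <- paste(meta$cell_type, meta$donor_id, sep = "||")
  raw <- rowsum(as.matrix(nuclei$counts), key)
  info <- tibble(key = rownames(raw)) |>
    tidyr::separate_wider_delim("key", "||",
                                names = c("cell_type", "donor_id")) |>
    mutate(n_cells = as.integer(table(key)[rownames(raw)])) |>
    left_join(meta |> distinct(.data$donor_id, .data$age, .data$age_group,
                               .data$sex, .data$batch),
              by = "donor_id")
  ok_types <- info |>
    group_by(.data$cell_type) |>
    summarise(n_ok = sum(.data$n_cells >= min_cells), .groups = "drop") |>
    filter(.data$n_ok >= min_donors) |>
    pull("cell_type")
  if (length(ok_types) == 0) abort("no cell types pass the pseudobulk rule")
  keep <- info$cell_type %in% ok_types
  raw <- raw[keep, , drop = FALSE]
  info <- info[keep, ]
  depth <- rowSums(raw)
  depth[depth == 0] <- 1
  mat <- log1p(raw / depth * 1e4)
  structure(list(mat = mat, raw = raw, meta = info), class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("<pseudobulk> ", nrow(x$mat), " pseudo-samples (",
      length(unique(x$meta$cell_type)), " cell types) x ", ncol(x$mat),
      " genes\n", sep = "")
  invisible(x)
}

#' Select balanced marker genes per cell type
#'
#' Per cell type, each gene is rank-tested (Wilcoxon rank-sum, BH-adjusted
#' within the type) on pseudo-samples of that type versus all other types.
#' Genes with mean log-fold change above `lfc_min` (difference of mean
#' normalised log expression, natural-log units) and adjusted p below
#' `padj_max` are retained. Each gene then receives a dispersion score --
#' its variance/mean ratio within each cell type, averaged across types --
#' and the global top `dispersion_drop` fraction by dispersion is
#' discarded. Finally lists are balanced by truncating every type's list
#' (strongest fold change first) to the smallest surviving count, and a
#' gene is assigned only to its best type so no gene appears twice.
#'
#' @param pb A [pseudobulk_nuclei()] result.
#' @param lfc_min Mean log-fold-change gate (default 1.25).
#' @param padj_max BH-adjusted p gate (default 0.05).
#' @param dispersion_drop Fraction of highest-dispersion genes removed
#'   (default 0.01).
#' @return A `marker_set`: tibble `gene`, `cell_type`, `lfc`, `padj`,
#'   `dispersion`, balanced across types.
#' @export
select_markers <- function(pb, lfc_min = 1.25, padj_max = 0.05,
                           dispersion_drop = 0.01) {
  stopifnot(inherits(pb, "pseudobulk"))
  types <- unique(pb$meta$cell_type)
  if (length(types) < 2) abort("need at least 2 cell types")

  # dispersion: variance/mean of normalised expression within type, averaged
  disp_by_type <- vapply(types, function(t) {
    m <- pb$mat[pb$meta$cell_type == t, , drop = FALSE]
    mu <- colMeans(m)
    v <- apply(m, 2, stats::var)
    ifelse(mu > 0, v / mu, 0)
  }, numeric(ncol(pb$mat)))
  dispersion <- rowMeans(disp_by_type)
  n_drop <- floor(dispersion_drop * length(dispersion))
  dropped <- if (n_drop > 0) {
    names(sort(dispersion, decreasing = TRUE))[seq_len(n_drop)]
  } else character(0)

  cand <- purrr::map(types, function(t) {
    in_t <- pb$meta$cell_type == t
    m1 <- pb$mat[in_t, , drop = FALSE]
    m0 <- pb$mat[!in_t, , drop = FALSE]
    lfc <- colMeans(m1) - colMeans(m0)
    p <- vapply(seq_len(ncol(pb$mat)), function(j) {
      suppressWarnings(wilcox.test(m1[, j], m0[, j])$p.value)
    }, numeric(1))
    tibble(gene = colnames(pb$mat), cell_type = t, lfc = lfc,
           padj = p.adjust(p, method = "BH"),
           dispersion = dispersion[colnames(pb$mat)]) |>
      filter(.data$lfc > lfc_min, .data$padj < padj_max,
             !.data$gene %in% dropped)
  }) |> bind_rows()

  # a gene belongs to its best type only
  cand <- cand |>
    group_by(.data$gene) |>
    slice(which.max(.data$lfc)) |>
    ungroup()

  per_type <- table(factor(cand$cell_type, levels = types))
  empty <- names(per_type)[per_type == 0]
  if (length(empty)) {
    abort(sprintf("no surviving markers for type(s): %s",
                  paste(empty, collapse = ", ")))
  }
  n_bal <- min(per_type)
  out <- cand |>
    group_by(.data$cell_type) |>
    arrange(dplyr::desc(.data$lfc), .by_group = TRUE) |>
    slice(seq_len(n_bal)) |>
    ungroup()
  structure(out, class = c("marker_set", class(out)),
            n_per_type = n_bal, dropped_dispersion = dropped)
}

#' Mean reference expression profiles over marker genes
#'
#' @param pb A [pseudobulk_nuclei()] result.
#' @param markers A [select_markers()] result (or tibble `gene`,
#'   `cell_type`).
#' @return Gene x cell-type matrix of mean normalised expression restricted
#'   to the marker genes.
#' @export
marker_reference <- function(pb, markers) {
  genes <- unique(markers$gene)
  types <- unique(pb$meta$cell_type)
  ref <- vapply(types, function(t) {
    colMeans(pb$mat[pb$meta$cell_type == t, genes, drop = FALSE])
  }, numeric(length(genes)))
  rownames(ref) <- genes
  ref
}

#' Per-spot cell-type composition by non-negative least squares
#'
#' A simple deconvolution stand-in: for each spot, finds non-negative
#' cell-type weights minimising the squared error between the spot's
#' normalised marker-gene expression and the weighted reference profiles,
#' then normalises weights to sum to 1. This is plumbing around the
#' composition tests, not a probabilistic deconvolution model.
#'
#' @param ds A `spatial_dataset` (its counts are depth-normalised to 10k
#'   and log1p-transformed over the marker genes), or a spot x gene matrix
#'   already on the reference's scale.
#' @param reference Gene x cell-type matrix from [marker_reference()].
#' @return Tibble `spot_id`, one weight column per cell type, and
#'   `degenerate` flagging all-zero spots (assigned uniform composition).
#' @export
deconvolve_nnls <- function(ds, reference) {
  if (inherits(ds, "spatial_dataset")) {
    genes <- intersect(rownames(reference), colnames(ds$counts))
    mat <- normalize_log1p(ds$counts)[, genes, drop = FALSE]
    ids <- ds$spot_meta$spot_id
  } else {
    genes <- intersect(rownames(reference), colnames(ds))
    mat <- as.matrix(ds)[, genes, drop = FALSE]
    ids <- rownames(ds) %||% sprintf("spot%d", seq_len(nrow(ds)))
  }
  if (length(genes) == 0) abort("no reference genes present in the data")
  A <- reference[genes, , drop = FALSE]
  K <- ncol(A)
  W <- matrix(0, nrow(mat), K, dimnames = list(NULL, colnames(A)))
  degenerate <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    b <- mat[i, ]
    if (all(b == 0)) {
      W[i, ] <- 1 / K
      degenerate[i] <- TRUE
    } else {
      w <- pracma::lsqnonneg(A, b)$x
      if (sum(w) == 0) {
        W[i, ] <- 1 / K
        degenerate[i] <- TRUE
      } else {
        W[i, ] <- w / sum(w)
      }
    }
  }
  bind_cols(tibble(spot_id = ids), as_tibble(W),
            tibble(degenerate = degenerate))
}

#' Wilcoxon tests of composition change between age groups
#'
#' Averages spot compositions per (donor, AAR) to independent batch
#' estimates and applies the Wilcoxon rank-sum test between age groups per
#' (cell type, AAR, comparison), with BH correction across the whole
#' family. Strata with fewer than 2 donors per group are skipped and
#' recorded.
#'
#' @param compositions Output of [deconvolve_nnls()].
#' @param spot_meta Spot metadata (`spot_id`, `donor_id`, `age_group`,
#'   `aar`).
#' @param comparisons List of group pairs.
#' @return Tibble `cell_type`, `aar`, `comparison`, `estimate` (difference
#'   of group median compositions), `p.value`, `q.value`, `skipped`.
#' @export
test_composition_age <- function(compositions, spot_meta,
                                 comparisons = list(c("old", "young"))) {
  types <- setdiff(colnames(compositions), c("spot_id", "degenerate"))
  long <- compositions |>
    select(-"degenerate") |>
    tidyr::pivot_longer(all_of(types), names_to = "cell_type",
                        values_to = "w") |>
    left_join(spot_meta |> select("spot_id", "donor_id", "age_group", "aar"),
              by = "spot_id") |>
    group_by(.data$cell_type, .data$donor_id, .data$age_group, .data$aar) |>
    summarise(w = mean(.data$w), .groups = "drop")
  res <- purrr::map(comparisons, function(cmp) {
    long |>
      filter(.data$age_group %in% cmp) |>
      group_by(.data$cell_type, .data$aar) |>
      dplyr::group_modify(function(d, key) {
        x <- d$w[d$age_group == cmp[1]]
        y <- d$w[d$age_group == cmp[2]]
        if (length(x) < 2 || length(y) < 2) {
          return(tibble(estimate = NA_real_, p.value = NA_real_,
                        skipped = TRUE))
        }
        if (sd(c(x, y)) == 0) {
          # every donor identical: all ranks tied, no evidence
          return(tibble(estimate = 0, p.value = 1, skipped = FALSE))
        }
        wt <- suppressWarnings(wilcox.test(x, y))
        tibble(estimate = median(x) - median(y),
               p.value = wt$p.value, skipped = FALSE)
      }) |>
      ungroup() |>
      mutate(comparison = paste(cmp, collapse = "_vs_"))
  }) |> bind_rows()
  res$q.value <- NA_real_
  ok <- !res$skipped
  res$q.value[ok] <- p.adjust(res$p.value[ok], method = "BH")
  res
}
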