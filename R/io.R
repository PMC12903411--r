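#' Write / read datasets as MatrixMarket counts with TSV sidecars
#'
#' Counts are stored in 1-based MatrixMarket coordinate format
#' (`counts.mtx`), spot or nucleus metadata in `spots.tsv` / `nuclei.tsv`,
#' and gene metadata (with biotype flags) in `genes.tsv`. A round trip
#' reproduces counts and metadata exactly.
#'
#' @param ds A `spatial_dataset` or `nuclei_dataset`.
#' @param dir Output directory (created if missing).
#' @param truth Optional ground-truth list; written to `ground_truth.json`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, truth = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(ds$counts, "CsparseMatrix"),
                  file.path(dir, "counts.mtx"))
  meta <- if (inherits(ds, "spatial_dataset")) ds$spot_meta else ds$nuc_meta
  meta_file <- if (inherits(ds, "spatial_dataset")) "spots.tsv" else "nuclei.tsv"
  readr::write_tsv(meta, file.path(dir, meta_file))
  readr::write_tsv(ds$gene_meta, file.path(dir, "genes.tsv"))
  if (!is.null(truth)) {
    jsonlite::write_json(truth_to_json(truth),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

truth_to_json <- function(truth) {
  out <- truth
  if (!is.null(out$beta)) {
    dn <- dimnames(out$beta)
    out$beta <- list(values = as.numeric(out$beta), dim = dim(out$beta),
                     aars = dn[[2]], groups = dn[[3]])
  }
  out
}

#' @rdname write_dataset
#' @export
read_spatial_dataset <- function(dir) {
  counts <- read_counts_mtx(dir)
  spot_meta <- readr::read_tsv(file.path(dir, "spots.tsv"),
                               show_col_types = FALSE) |>
    mutate(across(dplyr::any_of(c("row", "col")), as.integer))
  gene_meta <- readr::read_tsv(file.path(dir, "genes.tsv"),
                               show_col_types = FALSE)
  rownames(counts) <- spot_meta$spot_id
  colnames(counts) <- gene_meta$gene
  new_spatial_dataset(counts, spot_meta, gene_meta)
}

#' @rdname write_dataset
#' @export
read_nuclei_dataset <- function(dir) {
  counts <- read_counts_mtx(dir)
  nuc_meta <- readr::read_tsv(file.path(dir, "nuclei.tsv"),
                              show_col_types = FALSE) |>
    mutate(across(dplyr::any_of("n_umi"), as.integer))
  gene_meta <- readr::read_tsv(file.path(dir, "genes.tsv"),
                               show_col_types = FALSE)
  rownames(counts) <- nuc_meta$nucleus_id
  colnames(counts) <- gene_meta$gene
  new_nuclei_dataset(counts, nuc_meta, gene_meta)
}

read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "counts.mtx"))
  Matrix::Matrix(as.matrix(m), sparse = TRUE)
}
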