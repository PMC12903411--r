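# Shared fixtures, built once per test run.

flat_beta <- function(n_genes, value, groups = c("young", "old")) {
  array(value, dim = c(n_genes, 7, length(groups)),
        dimnames = list(NULL, c("L1", "L2", "L3", "L4", "L5", "L6", "WM"),
                        groups))
}

one_aar_bands <- function(nrows) {
  stats::setNames(c(nrows, 0, 0, 0, 0, 0, 0),
                  c("L1", "L2", "L3", "L4", "L5", "L6", "WM"))
}

# tiny spatial dataset with all three age groups, used by several files
.fixture_env <- new.env()

small_spatial <- function() {
  if (is.null(.fixture_env$spatial)) {
    cfg <- sim_config(
      n_donors_per_group = c(young = 2, middle = 2, old = 2),
      arrays_per_donor = 1, grid_shape = c(10, 10), n_genes = 60,
      theta = 0.1, baseline_log_rate = log(1), spatial_sd = 0.2,
      noise_sd = 0.1, seed = 101
    )
    .fixture_env$spatial <- generate_spatial_dataset(cfg)
  }
  .fixture_env$spatial
}

small_nuclei <- function() {
  if (is.null(.fixture_env$nuclei)) {
    cfg <- sim_config(
      n_donors_per_group = c(young = 3, middle = 3, old = 3),
      n_genes = 400, n_nuclei_per_donor = 80, nuclei_depth = 1500,
      seed = 202
    )
    .fixture_env$nuclei <- generate_nuclei_dataset(cfg)
  }
  .fixture_env$nuclei
}

# hand-built spatial dataset: explicit counts + coordinates on one array
manual_spatial <- function(counts, row, col, aar = NULL,
                           array_id = "a1", age_group = "young") {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(aar)) aar <- rep("L1", n)
  spot_meta <- tibble::tibble(
    spot_id = sprintf("s%02d", seq_len(n)),
    array_id = rep_len(array_id, n),
    donor_id = paste0(rep_len(age_group, n), "_d"),
    age_group = rep_len(age_group, n),
    sex = "M", age = 40, row = row, col = col, aar = aar
  )
  gene_meta <- tibble::tibble(
    gene = sprintf("G%05d", seq_len(ncol(counts))),
    biotype = rep("protein_coding", ncol(counts))
  )
  colnames(counts) <- gene_meta$gene
  rownames(counts) <- spot_meta$spot_id
  senespat:::new_spatial_dataset(
    Matrix::Matrix(counts, sparse = TRUE),
    spot_meta, gene_meta)
}

manual_nuclei <- function(counts, donor_id, age, age_group, sex = NULL,
                          batch = NULL, cell_type = "Oli",
                          biotype = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  gene_meta <- tibble::tibble(
    gene = colnames(counts) %||% sprintf("G%05d", seq_len(ncol(counts))),
    biotype = biotype %||% rep("protein_coding", ncol(counts))
  )
  colnames(counts) <- gene_meta$gene
  meta <- tibble::tibble(
    nucleus_id = sprintf("n%04d", seq_len(n)),
    donor_id = rep_len(donor_id, n),
    batch = rep_len(batch %||% "b1", n),
    age = rep_len(age, n),
    age_group = rep_len(age_group, n),
    sex = rep_len(sex %||% "M", n),
    cell_type = rep_len(cell_type, n),
    subcluster = "x.1",
    n_umi = as.integer(rowSums(counts)),
    mt_frac = 0
  )
  rownames(counts) <- meta$nucleus_id
  senespat:::new_nuclei_dataset(
    Matrix::Matrix(counts, sparse = TRUE),
    meta, gene_meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
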