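#' Generate a synthetic spatial transcriptomics dataset
#'
#' Emits spot-by-gene ZIP counts over square arrays with horizontal AAR bands
#' (L1 at the top through white matter at the bottom), donor/age-group/sex
#' metadata, and the planted ground truth. Counts for spot `s` and gene `g`
#' are structural zeros with probability `theta`, otherwise
#' Poisson(`exp(beta[g, aar(s), group(s)] + psi + eps)`), where `psi` is a
#' per-gene spatially smoothed field with marginal scale `spatial_sd` and
#' `eps` iid Normal(0, `noise_sd`) spot noise. With `spatial_sd = noise_sd
#' = 0` the empirical mean count of a gene in an AAR converges to
#' `(1 - theta) * exp(beta)` as spots accumulate.
#'
#' Sexes are assigned alternately within each age group for balance.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `dataset` (a `spatial_dataset`: `counts`
#'   sparse spot x gene matrix, `spot_meta`, `gene_meta` tibbles) and `truth`
#'   (a list with `beta` and `modules`).
#' @export
generate_spatial_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    donors <- donor_table(cfg)
    spots <- array_spot_table(cfg, donors)
    S <- nrow(spots)
    G <- cfg$n_genes

    aar_idx <- match(spots$aar, aar_levels())
    grp_idx <- match(spots$age_group, dimnames(cfg$beta_table)[[3]])

    # per-array neighbour structure reused for every gene's spatial field
    smoothers <- NULL
    if (cfg$spatial_sd > 0) {
      smoothers <- lapply(split(seq_len(S), spots$array_id), function(idx) {
        adjacency_matrix(spots$row[idx], spots$col[idx])
      })
      arr_split <- split(seq_len(S), spots$array_id)
    }

    counts <- matrix(0L, nrow = S, ncol = G)
    for (g in seq_len(G)) {
      eta <- cfg$beta_table[cbind(g, aar_idx, grp_idx)]
      if (cfg$spatial_sd > 0) {
        psi <- numeric(S)
        for (j in seq_along(arr_split)) {
          idx <- arr_split[[j]]
          psi[idx] <- car_field(smoothers[[j]], cfg$spatial_sd)
        }
        eta <- eta + psi
      }
      if (cfg$noise_sd > 0) eta <- eta + rnorm(S, 0, cfg$noise_sd)
      y <- rpois(S, exp(eta))
      if (cfg$theta > 0) {
        y[runif(S) < cfg$theta] <- 0L
      }
      counts[, g] <- y
    }

    gene_meta <- gene_metadata(cfg)
    colnames(counts) <- gene_meta$gene
    rownames(counts) <- spots$spot_id

    ds <- new_spatial_dataset(
      counts = Matrix::Matrix(counts, sparse = TRUE),
      spot_meta = spots,
      gene_meta = gene_meta
    )
    truth <- list(
      beta = cfg$beta_table,
      theta = cfg$theta,
      modules = planted_module_table(cfg, gene_meta$gene)
    )
    list(dataset = ds, truth = truth)
  })
}

# donor roster with alternating sexes within each group
donor_table <- function(cfg) {
  purrr::imap(cfg$n_donors_per_group, function(n, grp) {
    tibble(
      donor_id = sprintf("%s_d%02d", grp, seq_len(n)),
      age_group = grp,
      sex = rep_len(c("M", "F"), n),
      age = round(seq(age_range(grp)[1], age_range(grp)[2],
                      length.out = max(n, 2))[seq_len(n)])
    )
  }) |>
    bind_rows()
}

age_range <- function(grp) {
  switch(grp, young = c(28, 44), middle = c(45, 55), old = c(56, 88))
}

array_spot_table <- function(cfg, donors) {
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  band_of_row <- rep(names(cfg$aar_band_rows), cfg$aar_band_rows)
  per_array <- tibble(
    row = rep(seq_len(nr), each = nc),
    col = rep(seq_len(nc), times = nr),
    aar = band_of_row[rep(seq_len(nr), each = nc)]
  )
  arrays <- tidyr::expand_grid(
    donor_id = donors$donor_id,
    rep = seq_len(cfg$arrays_per_donor)
  ) |>
    mutate(array_id = sprintf("%s_a%d", .data$donor_id, .data$rep))
  spots <- tidyr::expand_grid(arrays, per_array) |>
    left_join(donors, by = "donor_id") |>
    mutate(spot_id = sprintf("%s_r%02dc%02d", .data$array_id,
                             .data$row, .data$col)) |>
    select("spot_id", "array_id", "donor_id", "age_group", "sex", "age",
           "row", "col", "aar")
  spots
}

# sparse rook adjacency for one array's spots
adjacency_matrix <- function(row, col) {
  n <- length(row)
  key <- paste(row, col)
  if (anyDuplicated(key)) abort("duplicate grid coordinates within an array")
  pos <- setNames(seq_len(n), key)
  from <- integer(0); to <- integer(0)
  for (d in list(c(0, 1), c(1, 0))) {
    nb <- paste(row + d[1], col + d[2])
    hit <- which(nb %in% names(pos))
    from <- c(from, hit)
    to <- c(to, pos[nb[hit]])
  }
  Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                       dims = c(n, n))
}

# spatially autocorrelated field: white noise smoothed twice over the rook
# neighbourhood, re-standardised to the requested marginal scale and centred
car_field <- function(adj, scale) {
  n <- nrow(adj)
  deg <- Matrix::rowSums(adj)
  z <- rnorm(n)
  for (i in 1:2) z <- (z + as.numeric(adj %*% z) / pmax(deg, 1)) / 2
  z <- z - mean(z)
  s <- sd(z)
  if (s > 0) z <- z / s * scale
  z
}

gene_metadata <- function(cfg) {
  G <- cfg$n_genes
  genes <- sprintf("G%05d", seq_len(G))
  biotype <- rep("protein_coding", G)
  n_m <- round(cfg$frac_mito * G)
  n_l <- round(cfg$frac_lnc * G)
  n_p <- round(cfg$frac_pseudo * G)
  # flagged biotypes occupy the tail of the index space so that planted
  # modules and hallmark lists (carved from the front) stay protein-coding
  flag_idx <- G - seq_len(n_m + n_l + n_p) + 1L
  if (n_m > 0) biotype[flag_idx[seq_len(n_m)]] <- "mito"
  if (n_l > 0) biotype[flag_idx[n_m + seq_len(n_l)]] <- "lncRNA"
  if (n_p > 0) biotype[flag_idx[n_m + n_l + seq_len(n_p)]] <- "pseudogene"
  tibble(gene = genes, biotype = biotype)
}

planted_module_table <- function(cfg, gene_names) {
  if (length(cfg$planted_modules) == 0) {
    return(tibble(gene = character(), module = character()))
  }
  purrr::imap(cfg$planted_modules, function(pm, i) {
    tibble(gene = gene_names[pm$genes], module = paste0("planted", i))
  }) |>
    bind_rows()
}

new_spatial_dataset <- function(counts, spot_meta, gene_meta) {
  stopifnot(nrow(counts) == nrow(spot_meta),
            ncol(counts) == nrow(gene_meta))
  structure(list(counts = counts, spot_meta = spot_meta,
                 gene_meta = gene_meta),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("<spatial_dataset> ", nrow(x$counts), " spots x ", ncol(x$counts),
      " genes, ", length(unique(x$spot_meta$array_id)), " arrays\n", sep = "")
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

# subset a spatial dataset by spot / gene index keeping metadata aligned
subset_spatial <- function(ds, spots = NULL, genes = NULL) {
  if (!is.null(genes)) {
    ds$counts <- ds$counts[, genes, drop = FALSE]
    ds$gene_meta <- ds$gene_meta[genes, , drop = FALSE]
  }
  if (!is.null(spots)) {
    ds$counts <- ds$counts[spots, , drop = FALSE]
    ds$spot_meta <- ds$spot_meta[spots, , drop = FALSE]
  }
  ds
}
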