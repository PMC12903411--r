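#' Generate a synthetic single-nucleus dataset with planted senescent nuclei
#'
#' Emits nucleus-by-gene counts matched to the spatial cohort's donor roster.
#' Each broad cell class has a distinct marker program: marker genes carved
#' for the class have their expression rate multiplied by `marker_boost`.
#' A nucleus's counts are Poisson draws with rates proportional to its class
#' program scaled to a LogNormal depth around `nuclei_depth`. Planted
#' senescent nuclei (per-class, per-age-group fractions from
#' `planted_senescence`) over-express the designated hallmark genes by the
#' configured fold `effect`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `dataset` (a `nuclei_dataset`: `counts` nucleus x gene
#'   sparse matrix, `nuc_meta`, `gene_meta`) and `truth` (`senescent` logical
#'   per nucleus, `markers` named list of per-class marker genes).
#' @export
generate_nuclei_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    donors <- donor_table(cfg)
    donors$batch <- paste0("b", (seq_len(nrow(donors)) - 1L) %/% 2L + 1L)
    gene_meta <- gene_metadata(cfg)
    G <- cfg$n_genes
    types <- cfg$cell_types
    markers <- carve_markers(cfg, gene_meta)

    # class programs: baseline 1 everywhere, markers boosted; mito genes get
    # a small constant rate so the MT fraction is non-trivial but below QC
    base <- matrix(1, nrow = length(types), ncol = G,
                   dimnames = list(types, gene_meta$gene))
    for (t in types) base[t, markers[[t]]] <- cfg$marker_boost
    mito <- gene_meta$biotype == "mito"
    if (any(mito)) base[, mito] <- 1.5

    props <- cfg$cell_type_props
    if (is.matrix(props)) {
      prop_for <- function(grp) props[grp, ]
    } else {
      prop_for <- function(grp) props
    }

    sen <- cfg$planted_senescence
    rows <- vector("list", nrow(donors))
    count_blocks <- vector("list", nrow(donors))
    for (d in seq_len(nrow(donors))) {
      n <- cfg$n_nuclei_per_donor
      grp <- donors$age_group[d]
      ct <- sample(types, n, replace = TRUE, prob = prop_for(grp)[types])
      is_sen <- rep(FALSE, n)
      if (!is.null(sen)) {
        fr <- sen$fraction[[grp]] %||% 0
        cand <- which(ct == sen$cell_type)
        k <- round(fr * length(cand))
        if (k > 0) is_sen[sample(cand, k)] <- TRUE
      }
      depth <- stats::rlnorm(n, log(cfg$nuclei_depth) - 0.125, 0.5)
      cnt <- matrix(0L, nrow = n, ncol = G)
      for (i in seq_len(n)) {
        rate <- base[ct[i], ]
        if (is_sen[i]) rate[sen$genes] <- rate[sen$genes] * sen$effect
        cnt[i, ] <- rpois(G, rate / sum(rate) * depth[i])
      }
      count_blocks[[d]] <- cnt
      rows[[d]] <- tibble(
        nucleus_id = sprintf("%s_n%04d", donors$donor_id[d], seq_len(n)),
        donor_id = donors$donor_id[d],
        batch = donors$batch[d],
        age = donors$age[d],
        age_group = grp,
        sex = donors$sex[d],
        cell_type = ct,
        subcluster = paste0(ct, ".1"),
        senescent_true = is_sen
      )
    }
    counts <- do.call(rbind, count_blocks)
    meta <- bind_rows(rows)
    colnames(counts) <- gene_meta$gene
    rownames(counts) <- meta$nucleus_id

    meta$n_umi <- as.integer(rowSums(counts))
    mt_cols <- which(gene_meta$biotype == "mito")
    meta$mt_frac <- if (length(mt_cols)) {
      rowSums(counts[, mt_cols, drop = FALSE]) / pmax(meta$n_umi, 1)
    } else 0

    ds <- new_nuclei_dataset(
      counts = Matrix::Matrix(counts, sparse = TRUE),
      nuc_meta = select(meta, -"senescent_true"),
      gene_meta = gene_meta
    )
    truth <- list(senescent = setNames(meta$senescent_true, meta$nucleus_id),
                  markers = markers)
    list(dataset = ds, truth = truth)
  })
}

# disjoint per-class marker gene sets from the front of the gene index space,
# offset so they do not collide with hallmark lists carved by
# generate_hallmark_genesets (which start right after the markers)
carve_markers <- function(cfg, gene_meta) {
  k <- cfg$n_markers_per_type
  types <- cfg$cell_types
  need <- k * length(types)
  ok <- which(gene_meta$biotype == "protein_coding")
  if (length(ok) < need) abort("not enough protein-coding genes for markers")
  idx <- ok[seq_len(need)]
  setNames(
    lapply(seq_along(types), function(i) {
      gene_meta$gene[idx[((i - 1) * k + 1):(i * k)]]
    }),
    types
  )
}

new_nuclei_dataset <- function(counts, nuc_meta, gene_meta) {
  stopifnot(nrow(counts) == nrow(nuc_meta),
            ncol(counts) == nrow(gene_meta))
  structure(list(counts = counts, nuc_meta = nuc_meta, gene_meta = gene_meta),
            class = "nuclei_dataset")
}

#' @export
print.nuclei_dataset <- function(x, ...) {
  cat("<nuclei_dataset> ", nrow(x$counts), " nuclei x ", ncol(x$counts),
      " genes, ", length(unique(x$nuc_meta$donor_id)), " donors\n", sep = "")
  invisible(x)
}

#' @export
dim.nuclei_dataset <- function(x) dim(x$counts)

subset_nuclei <- function(ds, nuclei = NULL, genes = NULL) {
  if (!is.null(genes)) {
    ds$counts <- ds$counts[, genes, drop = FALSE]
    ds$gene_meta <- ds$gene_meta[genes, , drop = FALSE]
  }
  if (!is.null(nuclei)) {
    ds$counts <- ds$counts[nuclei, , drop = FALSE]
    ds$nuc_meta <- ds$nuc_meta[nuclei, , drop = FALSE]
  }
  ds
}

#' Generate synthetic senescence hallmark gene lists
#'
#' Carves 3 multi-hallmark and 7 individual-hallmark gene lists from the
#' configured gene space (protein-coding genes only, skipping the cell-class
#' marker block), and records the complement pool from which the fixed
#' control set is drawn. The individual hallmarks follow the field's
#' vocabulary: cell-cycle arrest, SASP, DNA damage response, resistance to
#' apoptosis, increased lysosomal content, cell surface markers, and
#' activated p53 targets.
#'
#' @param cfg A [sim_config()].
#' @param multi_size,hallmark_size Genes per multi-hallmark / individual list.
#' @param control_n Size of the fixed control set drawn from the complement
#'   pool (default 2000).
#' @param overlap Number of genes each multi-hallmark list shares with the
#'   individual lists (multi-hallmark lists aggregate several hallmarks).
#' @return A `hallmark_sets` object: named lists `multi` and `individual`,
#'   the `control_pool` (genes in no list) and the fixed `control_set`.
#' @export
generate_hallmark_genesets <- function(cfg, multi_size = 40,
                                       hallmark_size = 25,
                                       control_n = 2000,
                                       overlap = 10) {
  stopifnot(inherits(cfg, "sim_config"))
  gene_meta <- gene_metadata(cfg)
  markers <- unlist(carve_markers(cfg, gene_meta), use.names = FALSE)
  avail <- setdiff(gene_meta$gene[gene_meta$biotype == "protein_coding"],
                   markers)
  ind_names <- c("arrest", "SASP", "DDR", "apoptosis_resistance",
                 "lysosome", "surface_markers", "p53_targets")
  need <- 7 * hallmark_size + 3 * max(multi_size - overlap, 0)
  if (length(avail) < need + control_n) {
    abort(sprintf(paste0("insufficient non-member genes for a %d-gene ",
                         "control pool (need %d + %d, have %d)"),
                  control_n, need, control_n, length(avail)))
  }
  with_seed(cfg$seed + 2L, {
    take <- function(n) {
      out <- avail[seq_len(n)]
      avail <<- avail[-seq_len(n)]
      out
    }
    individual <- setNames(
      lapply(ind_names, function(nm) take(hallmark_size)), ind_names)
    multi <- setNames(vector("list", 3), c("multi1", "multi2", "multi3"))
    for (m in names(multi)) {
      shared <- sample(unlist(individual, use.names = FALSE),
                       min(overlap, multi_size))
      multi[[m]] <- c(shared, take(multi_size - length(shared)))
    }
    pool <- setdiff(gene_meta$gene,
                    c(unlist(individual), unlist(multi)))
    control_set <- sample(pool, min(control_n, length(pool)))
    structure(
      list(multi = multi, individual = individual,
           control_pool = pool, control_set = control_set),
      class = "hallmark_sets"
    )
  })
}

#' @export
print.hallmark_sets <- function(x, ...) {
  cat("<hallmark_sets> ", length(x$multi), " multi-hallmark + ",
      length(x$individual), " individual lists; control pool ",
      length(x$control_pool), " genes (fixed set ",
      length(x$control_set), ")\n", sep = "")
  invisible(x)
}
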