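#' Gene-gene Pearson correlation over spots
#'
#' @param expr_matrix Spot x gene matrix of expression values (typically the
#'   posterior mean `lambda` from the spatial model, or normalised counts).
#' @return Symmetric gene x gene correlation matrix with unit diagonal.
#'   Zero-variance genes get correlation 0 against all others (logged).
#' @export
gene_correlation <- function(expr_matrix) {
  expr_matrix <- as.matrix(expr_matrix)
  if (nrow(expr_matrix) < 3) abort("need at least 3 spots")
  if (!all(is.finite(expr_matrix))) abort("expression matrix must be finite")
  sds <- apply(expr_matrix, 2, sd)
  flat <- sds == 0
  cr <- suppressWarnings(cor(expr_matrix))
  if (any(flat)) {
    inform(sprintf("gene_correlation: %d zero-variance gene(s) set to r = 0",
                   sum(flat)))
    cr[flat, ] <- 0
    cr[, flat] <- 0
  }
  diag(cr) <- 1
  cr
}

#' Cluster genes into coexpression modules (KNN graph + Leiden)
#'
#' Links each gene to its `k` most-correlated partners, takes the undirected
#' union of those directed lists as the graph (edge weights are the
#' correlations, negative weights floored at 0), and partitions it with the
#' Leiden algorithm (modularity objective) at the given resolution. Modules
#' below `min_size` are discarded and their genes marked unassigned (`NA`).
#' Modules are renamed `M1, M2, ...` in decreasing size order.
#'
#' @param corr Square symmetric gene correlation matrix with gene names.
#' @param k Neighbours per gene (default 10).
#' @param resolution Leiden resolution (spatial default 2; use smaller
#'   values for small gene sets -- resolution trades off against graph size).
#' @param min_size Minimum module size (default 50).
#' @param seed Seed for the Leiden refinement; fixed seeds give identical
#'   partitions.
#' @return A `module_partition`: tibble with columns `gene`, `module`
#'   (NA = unassigned), carrying `k`, `resolution`, `seed` and module
#'   `sizes` as attributes.
#' @export
graph_cluster <- function(corr, k = 10, resolution = 2, min_size = 50,
                          seed = 1L) {
  n <- nrow(corr)
  if (is.null(rownames(corr))) {
    rownames(corr) <- colnames(corr) <- sprintf("g%d", seq_len(n))
  }
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8))) {
    abort("`corr` must be symmetric")
  }
  if (k >= n) abort("`k` must be smaller than the number of genes")
  g <- knn_graph(corr, k)
  memb <- with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution,
                           n_iterations = 10)$membership
  })
  relabel_partition(tibble(gene = rownames(corr), raw = memb),
                    min_size = min_size, k = k,
                    resolution = resolution, seed = seed)
}

knn_graph <- function(corr, k) {
  n <- nrow(corr)
  d <- corr
  diag(d) <- -Inf
  nn <- t(apply(d, 1, function(r) order(r, decreasing = TRUE)[seq_len(k)]))
  el <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  el <- unique(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- pmax(corr[el], 0)
  igraph::V(g)$name <- rownames(corr)
  g
}

relabel_partition <- function(df, min_size, k, resolution, seed,
                              prefix = "M") {
  sizes <- table(df$raw)
  keep <- names(sizes)[sizes >= min_size]
  ord <- keep[order(-sizes[keep], as.numeric(keep))]
  lab <- setNames(paste0(prefix, seq_along(ord)), ord)
  out <- df |>
    mutate(module = ifelse(.data$raw %in% keep,
                           lab[as.character(.data$raw)], NA_character_)) |>
    select("gene", "module")
  structure(out, class = c("module_partition", class(out)),
            k = k, resolution = resolution, seed = seed,
            sizes = table(out$module))
}

#' Derive cell-type submodules within each spatial module
#'
#' Re-clusters each spatial module's member genes on single-nucleus
#' coexpression: nuclei counts are depth-normalised to 10k and
#' log1p-transformed, Pearson correlations recomputed over nuclei for the
#' module's genes, and the KNN+Leiden procedure re-applied (defaults k = 10,
#' resolution = 1). Submodules are namespaced `M<i>.<j>`. Module genes
#' absent from the nuclei matrix are excluded (logged); modules with a
#' single usable gene become a singleton submodule.
#'
#' @param partition A `module_partition` from [graph_cluster()].
#' @param nuclei A QC'd `nuclei_dataset`.
#' @inheritParams graph_cluster
#' @return A `module_partition` tibble with columns `gene`, `module`,
#'   `submodule`.
#' @export
derive_submodules <- function(partition, nuclei, k = 10, resolution = 1,
                              seed = 1L) {
  stopifnot(inherits(nuclei, "nuclei_dataset"))
  norm <- normalize_log1p(nuclei$counts)
  out <- partition |>
    filter(!is.na(.data$module)) |>
    group_by(.data$module) |>
    dplyr::group_modify(function(d, key) {
      genes <- d$gene
      present <- genes[genes %in% colnames(norm)]
      if (length(present) < length(genes)) {
        inform(sprintf("derive_submodules: %d gene(s) of %s absent from nuclei data",
                       length(genes) - length(present), key$module))
      }
      if (length(present) == 0) return(tibble(gene = genes, sub = NA_integer_))
      if (length(present) <= 2) {
        sub <- setNames(rep(1L, length(present)), present)
      } else {
        cr <- gene_correlation(norm[, present, drop = FALSE])
        kk <- min(k, length(present) - 1)
        g <- knn_graph(cr, kk)
        memb <- with_seed(seed, {
          igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = 10)$membership
        })
        # renumber submodules by decreasing size
        sz <- table(memb)
        newid <- setNames(seq_along(sz), names(sz)[order(-sz)])
        sub <- setNames(newid[as.character(memb)], present)
      }
      tibble(gene = genes, sub = unname(sub[genes]))
    }) |>
    ungroup() |>
    mutate(submodule = ifelse(is.na(.data$sub), NA_character_,
                              paste0(.data$module, ".", .data$sub))) |>
    select("gene", "module", "submodule")
  missing <- partition |> filter(is.na(.data$module)) |>
    mutate(submodule = NA_character_)
  out <- bind_rows(out, missing) |>
    arrange(match(.data$gene, partition$gene))
  structure(out, class = c("module_partition", class(tibble())),
            k = k, resolution = resolution, seed = seed)
}

#' Score a gene module across spots (clip, scale, average)
#'
#' Each member gene's expression is clipped at its 99th percentile across
#' all spots (type-7, linear interpolation), standard-scaled (z-score across
#' spots), and the spot score is the mean over member genes. Genes constant
#' after clipping contribute 0 (logged). This removes differences in basal
#' expression so modules describe shared spatial pattern, not magnitude.
#'
#' @param expr_matrix Spot x gene matrix (posterior mean expression or
#'   normalised counts) with gene names and spot-id rownames.
#' @param member_genes Character vector of module member genes.
#' @param clip_q Clipping quantile (default 0.99).
#' @return Tibble `spot_id`, `score`.
#' @export
score_module_spots <- function(expr_matrix, member_genes, clip_q = 0.99) {
  expr_matrix <- as.matrix(expr_matrix)
  miss <- setdiff(member_genes, colnames(expr_matrix))
  if (length(miss)) {
    abort(sprintf("member gene(s) not in matrix: %s",
                  paste(head(miss, 3), collapse = ", ")))
  }
  sub <- expr_matrix[, member_genes, drop = FALSE]
  scaled <- apply(sub, 2, function(v) {
    if (!is.null(clip_q)) {
      cap <- quantile7(v, clip_q)
      v <- pmin(v, cap)
    }
    s <- sd(v)
    if (s == 0) {
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  })
  n_flat <- sum(apply(scaled, 2, function(v) all(v == 0)))
  if (n_flat > 0) {
    inform(sprintf("score_module_spots: %d constant gene(s) contribute 0",
                   n_flat))
  }
  tibble(spot_id = rownames(expr_matrix) %||%
           sprintf("spot%d", seq_len(nrow(expr_matrix))),
         score = unname(rowMeans(scaled)))
}

#' Score every module of a partition and aggregate per (array, AAR)
#'
#' Convenience wrapper around [score_module_spots()] for all modules (or
#' submodules) of a partition, joined with spot metadata and aggregated to
#' independent batch estimates: the mean score per (array, AAR, module),
#' which is the unit used for age-group testing.
#'
#' @inheritParams score_module_spots
#' @param partition A `module_partition`.
#' @param spot_meta Spot metadata tibble (`spot_id`, `array_id`, `donor_id`,
#'   `age_group`, `aar`).
#' @param level `"module"` or `"submodule"`.
#' @return A list with `spot_scores` (spot x module long tibble) and
#'   `batch_scores` (per array x AAR x module means with group labels).
#' @export
score_modules <- function(expr_matrix, partition, spot_meta,
                          level = c("module", "submodule"), clip_q = 0.99) {
  level <- match.arg(level)
  ids <- unique(stats::na.omit(partition[[level]]))
  spot_scores <- purrr::map(ids, function(m) {
    genes <- partition$gene[!is.na(partition[[level]]) &
                              partition[[level]] == m]
    score_module_spots(expr_matrix, genes, clip_q = clip_q) |>
      mutate(module = m)
  }) |> bind_rows()
  batch_scores <- spot_scores |>
    left_join(spot_meta, by = "spot_id") |>
    group_by(.data$module, .data$array_id, .data$donor_id,
             .data$age_group, .data$aar) |>
    summarise(score = mean(.data$score), n_spots = n(), .groups = "drop")
  list(spot_scores = spot_scores, batch_scores = batch_scores)
}

#' Welch's t-test of module scores between age groups
#'
#' Tests each (module, AAR) for a difference in per-array batch scores
#' between two age groups with Welch's t-test, correcting across the whole
#' family of (module x AAR x comparison) tests with Benjamini-Hochberg.
#' Groups with fewer than 2 arrays in a stratum are skipped and recorded.
#'
#' @param batch_scores Per-(array, AAR, module) scores as produced by
#'   [score_modules()].
#' @param comparisons List of `c(group1, group2)` pairs (default old vs
#'   young and middle vs young).
#' @return Tibble with `module`, `aar`, `comparison`, `estimate` (group1 -
#'   group2 mean difference), `statistic`, `p.value`, `q.value`, `tier`
#'   (signif codes at q < 0.05 / 1e-2 / 1e-3 / 1e-4), `skipped`.
#' @export
test_scores_by_age <- function(batch_scores,
                               comparisons = list(c("old", "young"),
                                                  c("middle", "young"))) {
  res <- purrr::map(comparisons, function(cmp) {
    batch_scores |>
      filter(.data$age_group %in% cmp) |>
      group_by(.data$module, .data$aar) |>
      dplyr::group_modify(function(d, key) {
        x <- d$score[d$age_group == cmp[1]]
        y <- d$score[d$age_group == cmp[2]]
        if (length(x) < 2 || length(y) < 2) {
          return(tibble(estimate = NA_real_, statistic = NA_real_,
                        p.value = NA_real_, skipped = TRUE))
        }
        if (sd(c(x, y)) == 0) {
          # all scores identical: no evidence of difference
          return(tibble(estimate = 0, statistic = 0, p.value = 1,
                        skipped = FALSE))
        }
        tt <- t.test(x, y)  # Welch by default
        tibble(estimate = mean(x) - mean(y),
               statistic = unname(tt$statistic),
               p.value = tt$p.value, skipped = FALSE)
      }) |>
      ungroup() |>
      mutate(comparison = paste(cmp, collapse = "_vs_"))
  }) |> bind_rows()
  res$q.value <- NA_real_
  ok <- !res$skipped
  res$q.value[ok] <- p.adjust(res$p.value[ok], method = "BH")
  res |>
    mutate(tier = dplyr::case_when(
      is.na(.data$q.value) ~ "",
      .data$q.value < 1e-4 ~ "****",
      .data$q.value < 1e-3 ~ "***",
      .data$q.value < 1e-2 ~ "**",
      .data$q.value < 0.05 ~ "*",
      TRUE ~ ""
    ))
}
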