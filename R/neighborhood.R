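#' Per-spot gene-set score on normalised spot expression
#'
#' Spot counts are depth-normalised to 10k and log1p-transformed; the score
#' is the mean over set genes minus the mean over a control gene set drawn
#' from genes outside the set (deterministic given `seed`).
#'
#' @param ds A `spatial_dataset`.
#' @param gene_set Character vector of set genes (non-empty).
#' @param control_set Optional explicit control genes; if `NULL`,
#'   `control_n` genes are sampled from outside `gene_set` (all available
#'   are used, with a log, if fewer).
#' @param control_n Control pool size (default 2000).
#' @param seed Seed for control sampling.
#' @return Tibble `spot_id`, `score`.
#' @export
score_spots <- function(ds, gene_set, control_set = NULL, control_n = 2000,
                        seed = 1L) {
  stopifnot(inherits(ds, "spatial_dataset"))
  gene_set <- intersect(gene_set, colnames(ds$counts))
  if (length(gene_set) == 0) abort("empty gene set")
  if (is.null(control_set)) {
    pool <- setdiff(colnames(ds$counts), gene_set)
    if (length(pool) < control_n) {
      inform(sprintf("score_spots: control pool has only %d genes; using all",
                     length(pool)))
      control_set <- pool
    } else {
      control_set <- with_seed(seed, sample(pool, control_n))
    }
  }
  norm <- normalize_log1p(ds$counts[, c(gene_set, control_set),
                                    drop = FALSE])
  score <- rowMeans(norm[, gene_set, drop = FALSE]) -
    rowMeans(norm[, control_set, drop = FALSE])
  tibble(spot_id = ds$spot_meta$spot_id, score = unname(score))
}

#' Assign global decile labels to spot scores
#'
#' Decile cut points (type-7 quantiles at 10%, ..., 90%) are computed over
#' all spots pooled (all arrays and age groups), and each spot gets a label
#' 1 (lowest) to 10 (highest). Tied scores at a cut point share the lower
#' label. Constant scores are degenerate: all spots get label 1 and the
#' result is flagged.
#'
#' @param scores Numeric vector, or the tibble from [score_spots()].
#' @return Integer labels 1..10 (same length/order as the input), with
#'   attribute `degenerate` if the scores were constant.
#' @export
assign_deciles <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) < 10) abort("need at least 10 spots")
  if (max(scores) == min(scores)) {
    warn("assign_deciles: constant scores; all spots labelled 1")
    out <- rep(1L, length(scores))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cuts <- quantile7(scores, seq(0.1, 0.9, by = 0.1))
  # duplicated cut points (heavy ties) compress neighbouring labels
  out <- as.integer(1L + findInterval(scores, unique(cuts), left.open = TRUE))
  attr(out, "degenerate") <- FALSE
  out
}

#' Pairwise decile neighborhood enrichment by within-array permutation
#'
#' Counts, over the spot graph restricted to a group of spots, how often
#' spots of decile `i` neighbour spots of decile `j` (unordered pairs;
#' `O` is symmetric), then compares against a permutation null in which
#' labels are shuffled independently within each array (arrays are
#' batches). The enrichment z-score is `(O - mean_perm) / sd_perm` with the
#' sample (n-1) sd; entries whose permutation sd is 0 are flagged
#' undefined (`NA`).
#'
#' @param labels Integer decile labels (1..`n_levels`) for every spot of
#'   the graph.
#' @param graph A [build_spot_graph()] on the same spots.
#' @param group_mask Optional logical mask (e.g. one age group); edges with
#'   either end outside the mask are ignored.
#' @param n_levels Number of label levels (default 10).
#' @param n_perm Permutations (default 1000).
#' @param seed Seed of the permutation stream.
#' @return An `enrichment_matrix`: list with `z`, `observed`, `perm_mean`,
#'   `perm_sd` (`n_levels x n_levels` symmetric matrices) and `n_perm`.
#' @export
pairwise_enrichment <- function(labels, graph, group_mask = NULL,
                                n_levels = 10, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(graph, "spot_graph"))
  labels <- as.integer(labels)
  if (length(labels) != graph$n) abort("labels must cover every spot")
  if (is.null(group_mask)) group_mask <- rep(TRUE, graph$n)
  if (!any(group_mask)) abort("empty group")
  e <- graph$edges
  keep <- group_mask[e[, 1]] & group_mask[e[, 2]]
  e <- e[keep, , drop = FALSE]
  if (nrow(e) == 0) abort("no edges within the group mask")

  pair_counts <- function(lab) {
    i <- pmin(lab[e[, 1]], lab[e[, 2]])
    j <- pmax(lab[e[, 1]], lab[e[, 2]])
    m <- matrix(0, n_levels, n_levels)
    tab <- table(factor(i, levels = seq_len(n_levels)),
                 factor(j, levels = seq_len(n_levels)))
    m <- m + as.matrix(tab)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  obs <- pair_counts(labels)

  arr <- graph$array_id
  idx_by_array <- split(which(group_mask), arr[group_mask])
  sums <- matrix(0, n_levels, n_levels)
  sq <- matrix(0, n_levels, n_levels)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      lab_p <- labels
      for (idx in idx_by_array) {
        lab_p[idx] <- labels[idx][sample.int(length(idx))]
      }
      m <- pair_counts(lab_p)
      sums <- sums + m
      sq <- sq + m^2
    }
  })
  mu <- sums / n_perm
  v <- (sq - n_perm * mu^2) / (n_perm - 1)
  v[v < 0] <- 0
  sdp <- sqrt(v)
  z <- (obs - mu) / sdp
  z[sdp == 0] <- NA_real_
  if (any(sdp == 0)) {
    warn("pairwise_enrichment: cells with zero permutation sd flagged NA")
  }
  structure(list(z = z, observed = obs, perm_mean = mu, perm_sd = sdp,
                 n_perm = n_perm),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("<enrichment_matrix> ", nrow(x$z), "x", ncol(x$z), " deciles, ",
      x$n_perm, " permutations; mean diagonal z ",
      sprintf("%.2f", mean(diag(x$z), na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}
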