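#' Single-nucleus gene-set module score with bin-matched controls
#'
#' The classic control-subtracted module score: normalise counts to 10k per
#' nucleus and log1p-transform; bin all genes involved (gene set plus the
#' fixed control set) into `n_bins` expression bins by their average
#' normalised expression; for each gene-set gene draw `ctrl_per_gene`
#' control genes from the same bin of the fixed control set; the score is
#' the mean normalised expression of the set genes minus the mean of the
#' selected controls, per nucleus. Bins with no control genes fall back to
#' the whole control set (logged). Deterministic given `seed`.
#'
#' @param nuclei A QC'd `nuclei_dataset`.
#' @param gene_set Character vector of set genes.
#' @param control_set Fixed control gene pool (disjoint from `gene_set`),
#'   e.g. the 2,000-gene control set from [generate_hallmark_genesets()].
#' @param n_bins Expression bins (default 24).
#' @param ctrl_per_gene Controls sampled per set gene (default 100,
#'   truncated to bin size).
#' @param seed Seed for control sampling.
#' @return Tibble `nucleus_id`, `score`.
#' @export
nuclei_module_score <- function(nuclei, gene_set, control_set,
                                n_bins = 24, ctrl_per_gene = 100,
                                seed = 1L) {
  stopifnot(inherits(nuclei, "nuclei_dataset"))
  if (length(intersect(gene_set, control_set))) {
    abort("control set must be disjoint from the gene set")
  }
  gene_set <- intersect(gene_set, colnames(nuclei$counts))
  control_set <- intersect(control_set, colnames(nuclei$counts))
  if (length(gene_set) == 0) abort("no gene-set genes present in the data")
  if (length(control_set) == 0) abort("no control genes present in the data")

  all_genes <- c(gene_set, control_set)
  norm <- normalize_log1p(nuclei$counts[, all_genes, drop = FALSE])
  avg <- colMeans(norm)
  brk <- unique(quantile7(avg, seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(avg, breaks = brk, include.lowest = TRUE, labels = FALSE)
  names(bin) <- all_genes

  ctrl <- with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      pool <- control_set[bin[control_set] == bin[g]]
      if (length(pool) == 0) pool <- control_set  # fallback, logged below
      sample(pool, min(ctrl_per_gene, length(pool)))
    }))
  })
  n_fallback <- sum(vapply(gene_set, function(g) {
    sum(bin[control_set] == bin[g]) == 0
  }, logical(1)))
  if (n_fallback > 0) {
    inform(sprintf(
      "nuclei_module_score: %d set gene(s) had empty control bins; whole control set used",
      n_fallback))
  }
  score <- rowMeans(norm[, gene_set, drop = FALSE]) -
    rowMeans(norm[, ctrl, drop = FALSE])
  tibble(nucleus_id = rownames(nuclei$counts), score = unname(score))
}

#' Score all hallmark lists for every nucleus
#'
#' Runs [nuclei_module_score()] for each multi-hallmark and individual
#' hallmark list, returning a long tibble joined with the nucleus metadata.
#'
#' @param nuclei A QC'd `nuclei_dataset`.
#' @param hallmarks A `hallmark_sets` object.
#' @inheritParams nuclei_module_score
#' @return Tibble `nucleus_id`, `hallmark`, `kind` (multi/individual),
#'   `score`, plus `cell_type`, `age_group`, `donor_id`, `batch`, `sex`.
#' @export
score_hallmarks <- function(nuclei, hallmarks, n_bins = 24,
                            ctrl_per_gene = 100, seed = 1L) {
  stopifnot(inherits(hallmarks, "hallmark_sets"))
  sets <- c(hallmarks$multi, hallmarks$individual)
  kind <- c(rep("multi", length(hallmarks$multi)),
            rep("individual", length(hallmarks$individual)))
  purrr::imap(sets, function(genes, nm) {
    nuclei_module_score(nuclei, genes, hallmarks$control_set,
                        n_bins = n_bins, ctrl_per_gene = ctrl_per_gene,
                        seed = seed) |>
      mutate(hallmark = nm)
  }) |>
    bind_rows() |>
    left_join(tibble(hallmark = names(sets), kind = kind), by = "hallmark") |>
    left_join(nuclei$nuc_meta |>
                select("nucleus_id", "cell_type", "age_group",
                       "donor_id", "batch", "sex"),
              by = "nucleus_id")
}

#' Young-referenced positivity thresholds
#'
#' For each (hallmark, broad class) stratum the positivity threshold is the
#' 95th percentile (type-7) of the young age group's module scores. Strata
#' with fewer than `min_young` young nuclei get an undefined threshold and
#' downstream positivity is marked missing.
#'
#' @param scores Long score tibble from [score_hallmarks()] (needs columns
#'   `score`, `hallmark`, `cell_type`, `age_group`).
#' @param q Quantile (default 0.95, i.e. the top-5% rule).
#' @param min_young Minimum young nuclei per stratum (default 20).
#' @return Tibble `hallmark`, `cell_type`, `threshold`, `n_young`.
#' @export
positivity_thresholds <- function(scores, q = 0.95, min_young = 20) {
  scores |>
    group_by(.data$hallmark, .data$cell_type) |>
    summarise(
      n_young = sum(.data$age_group == "young"),
      threshold = if (sum(.data$age_group == "young") >= min_young) {
        quantile7(.data$score[.data$age_group == "young"], q)
      } else NA_real_,
      .groups = "drop"
    )
}

#' Classify nuclei as hallmark-positive
#'
#' A nucleus is positive for a hallmark when its module score is strictly
#' greater than the threshold of its (hallmark, broad class) stratum. The
#' multi-hallmark burden counts positives among the 7 individual hallmarks
#' only; `three_plus` flags nuclei positive for at least three of them.
#'
#' @param scores Long score tibble from [score_hallmarks()].
#' @param thresholds From [positivity_thresholds()].
#' @return A list: `table` (per nucleus x hallmark: `score`, `threshold`,
#'   `positive`) and `summary` (per nucleus: `n_individual_positive`,
#'   `three_plus`).
#' @export
classify_positive <- function(scores, thresholds) {
  tab <- scores |>
    left_join(thresholds, by = c("hallmark", "cell_type")) |>
    mutate(positive = ifelse(is.na(.data$threshold), NA,
                             .data$score > .data$threshold))
  summary <- tab |>
    filter(.data$kind == "individual") |>
    group_by(.data$nucleus_id, .data$cell_type, .data$age_group,
             .data$donor_id, .data$batch, .data$sex) |>
    summarise(
      n_individual_positive = sum(.data$positive, na.rm = TRUE),
      three_plus = sum(.data$positive, na.rm = TRUE) >= 3,
      .groups = "drop"
    )
  list(table = tab, summary = summary)
}

#' Transcript-positivity fraction per donor and its age trend
#'
#' Labels nuclei of one broad class positive when the given gene's
#' transcript count is greater than zero (the "p16+" rule for *CDKN2A*),
#' computes the per-donor positive percentage, and regresses it on donor
#' age with ordinary least squares.
#'
#' @param nuclei A `nuclei_dataset`.
#' @param gene Gene whose transcript positivity is assessed (default
#'   "CDKN2A").
#' @param cell_class Broad class to restrict to (default oligodendrocytes).
#' @return A `positivity_trend`: list with `per_donor` (tibble `donor_id`,
#'   `age`, `n`, `pct_positive`), `slope` (per year, percentage points),
#'   `p`, `r2`. Supports [tidy()] and [glance()].
#' @export
cdkn2a_positivity <- function(nuclei, gene = "CDKN2A", cell_class = "Oli") {
  stopifnot(inherits(nuclei, "nuclei_dataset"))
  if (!gene %in% colnames(nuclei$counts)) {
    abort(sprintf("gene '%s' not found", gene))
  }
  sel <- nuclei$nuc_meta$cell_type == cell_class
  pos <- as.numeric(nuclei$counts[sel, gene] > 0)
  d <- nuclei$nuc_meta[sel, ] |>
    mutate(pos = pos) |>
    group_by(.data$donor_id, .data$age) |>
    summarise(n = n(), pct_positive = 100 * mean(.data$pos),
              .groups = "drop")
  dropped <- setdiff(unique(nuclei$nuc_meta$donor_id), d$donor_id)
  if (length(dropped)) {
    inform(sprintf("cdkn2a_positivity: %d donor(s) with no %s nuclei excluded",
                   length(dropped), cell_class))
  }
  fit <- lm(pct_positive ~ age, data = d)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  structure(
    list(per_donor = d,
         slope = unname(coef(fit)["age"]),
         intercept = unname(coef(fit)[1]),
         p = if (nrow(d) > 2) sm$coefficients["age", 4] else NA_real_,
         r2 = sm$r.squared,
         gene = gene, cell_class = cell_class),
    class = "positivity_trend"
  )
}

#' @export
print.positivity_trend <- function(x, ...) {
  cat("<positivity_trend> ", x$gene, "+ fraction in ", x$cell_class,
      ": slope ", sprintf("%.4f", x$slope), " %/year, R2 ",
      sprintf("%.3f", x$r2), ", p ", format.pval(x$p), "\n", sep = "")
  invisible(x)
}

#' Test hallmark positivity differences between age groups
#'
#' For each (broad class, hallmark), tests the difference in the proportion
#' of positive nuclei between two age groups: a mixed-effects logistic
#' regression via [masc_test()] with batch as the random effect (the
#' senescence convention), plus a one-sided difference-of-proportions t
#' statistic on donor-level positivity fractions for heatmap display
#' (positive statistic = enrichment in `group1`). Strata where both groups
#' have zero positives return statistic 0 and p 1.
#'
#' @param positivity Output of [classify_positive()].
#' @param comparison `c(group1, group2)`.
#' @param random Random-effect factors passed to [masc_test()] (default
#'   batch only).
#' @return Tibble `cell_type`, `hallmark`, `comparison`, `or`, `p_masc`,
#'   `prop_stat`, `p_prop`, `separated`.
#' @export
test_positivity_by_age <- function(positivity, comparison = c("old", "young"),
                                   random = "batch") {
  tab <- positivity$table |> filter(!is.na(.data$positive))
  tab |>
    distinct(.data$cell_type, .data$hallmark) |>
    purrr::pmap(function(cell_type, hallmark) {
      d <- tab[tab$cell_type == cell_type & tab$hallmark == hallmark, ]
      m <- masc_test(d, indicator = d$positive, comparison = comparison,
                     random = random)
      # donor-level one-sided difference of proportions (Welch t)
      don <- d |>
        filter(.data$age_group %in% comparison) |>
        group_by(.data$donor_id, .data$age_group) |>
        summarise(frac = mean(.data$positive), .groups = "drop")
      x <- don$frac[don$age_group == comparison[1]]
      y <- don$frac[don$age_group == comparison[2]]
      if (length(x) < 2 || length(y) < 2 || sd(c(x, y)) == 0) {
        stat <- 0; pp <- 1
      } else {
        tt <- t.test(x, y, alternative = "greater")
        stat <- unname(tt$statistic); pp <- tt$p.value
      }
      tibble(cell_type = cell_type, hallmark = hallmark,
             comparison = m$comparison, or = m$or, p_masc = m$p,
             prop_stat = stat, p_prop = pp, separated = m$separated)
    }) |>
    bind_rows()
}
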