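# Correlation, KNN+Leiden modules, submodules, scoring, age testing.

test_that("gene correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  m <- cbind(a = x, b = y, dup = x, neg = -x, flat = c(2, 2, 2))
  cr <- suppressMessages(gene_correlation(m))
  expect_equal(cr["a", "b"], 0.9820, tolerance = 1e-4)
  expect_equal(cr["a", "dup"], 1)
  expect_equal(cr["a", "neg"], -1)
  expect_equal(unname(cr["flat", "a"]), 0)
  expect_equal(unname(diag(cr)), rep(1, 5))
  expect_true(isSymmetric(cr))
  expect_true(all(cr >= -1 & cr <= 1))
})

test_that("planted correlation blocks are recovered by KNN + Leiden", {
  set.seed(5)
  S <- 400
  f1 <- rnorm(S); f2 <- rnorm(S)
  mat <- cbind(
    sapply(1:100, function(i) f1 + rnorm(S) / 3),
    sapply(1:100, function(i) f2 + rnorm(S) / 3)
  )
  colnames(mat) <- sprintf("g%03d", 1:200)
  cr <- gene_correlation(mat)
  expect_gt(min(cr[1:100, 1:100]), 0.8)
  part <- graph_cluster(cr, k = 10, resolution = 1, min_size = 50, seed = 1)
  expect_identical(sort(unique(part$module)), c("M1", "M2"))
  expect_length(unique(part$module[1:100]), 1)
  expect_length(unique(part$module[101:200]), 1)
  expect_false(part$module[1] == part$module[101])

  # determinism under a fixed seed
  part2 <- graph_cluster(cr, k = 10, resolution = 1, min_size = 50, seed = 1)
  expect_identical(part$module, part2$module)

  # size filter: a 30-gene block is dropped at min_size = 50
  f3 <- rnorm(S)
  mat3 <- cbind(mat, sapply(1:30, function(i) f3 + rnorm(S) / 3))
  colnames(mat3) <- sprintf("g%03d", 1:230)
  part3 <- graph_cluster(gene_correlation(mat3), k = 10, resolution = 1,
                         min_size = 50, seed = 1)
  expect_true(all(is.na(part3$module[201:230])))
  expect_false(any(is.na(part3$module[1:200])))

  expect_error(graph_cluster(cr[1:5, 1:5], k = 10), "smaller")
})

test_that("submodules split along cell-type programs in nuclei data", {
  # one spatial module whose genes divide into an Ast-only and an Exc-only
  # program in the nuclei
  cfg <- sim_config(n_donors_per_group = c(young = 2, old = 2),
                    n_genes = 200, cell_types = c("Ast", "Exc"),
                    n_markers_per_type = 20, marker_boost = 12,
                    n_nuclei_per_donor = 150, nuclei_depth = 3000,
                    seed = 61)
  out <- generate_nuclei_dataset(cfg)
  nuclei <- out$dataset
  mk <- out$truth$markers
  genes <- c(mk$Ast, mk$Exc)
  part <- structure(tibble::tibble(gene = genes, module = "M1"),
                    class = c("module_partition", class(tibble::tibble())))
  sub <- suppressMessages(derive_submodules(part, nuclei, k = 5,
                                            resolution = 1, seed = 2))
  expect_true(all(grepl("^M1\\.\\d+$", sub$submodule)))
  # the planted split is recovered: each marker set maps to one submodule
  s_ast <- unique(sub$submodule[sub$gene %in% mk$Ast])
  s_exc <- unique(sub$submodule[sub$gene %in% mk$Exc])
  expect_length(s_ast, 1)
  expect_length(s_exc, 1)
  expect_false(s_ast == s_exc)

  # depth normalisation: 20k UMIs with gene count 20 -> log1p(10)
  norm <- senespat:::normalize_log1p(matrix(c(20, 19980), 1, 2))
  expect_equal(norm[1, 1], log1p(10))

  # single-gene module: one singleton submodule, no crash
  p1 <- structure(tibble::tibble(gene = mk$Ast[1], module = "M9"),
                  class = c("module_partition", class(tibble::tibble())))
  s1 <- suppressMessages(derive_submodules(p1, nuclei))
  expect_identical(s1$submodule, "M9.1")
})

test_that("module scores follow the clip / scale / average recipe", {
  # hand-computed: 5 spots, one gene (1,2,3,4,100), clip at q99 then scale
  v <- c(1, 2, 3, 4, 100)
  cap <- unname(quantile(v, 0.99, type = 7))  # 96.16
  vc <- pmin(v, cap)
  expected <- (vc - mean(vc)) / sd(vc)
  m <- matrix(v, ncol = 1, dimnames = list(sprintf("s%d", 1:5), "g1"))
  sc <- score_module_spots(m, "g1")
  expect_equal(sc$score, unname(expected))
  expect_lt(max(sc$score), (100 - mean(vc)) / sd(vc))

  # duplicated member gives identical scores to the single-gene case
  m2 <- cbind(m, g2 = v)
  sc2 <- score_module_spots(m2, c("g1", "g2"))
  expect_equal(sc2$score, sc$score)

  # affine rescaling of one member is absorbed by the z-scale
  # (clipping disabled to avoid cap interactions)
  m3 <- cbind(g1 = v, g2 = 5 + 3 * v)
  rownames(m3) <- sprintf("s%d", 1:5)
  sc3 <- score_module_spots(m3, c("g1", "g2"), clip_q = NULL)
  sc1 <- score_module_spots(cbind(g1 = v, g2 = v) |>
                              `rownames<-`(sprintf("s%d", 1:5)),
                            c("g1", "g2"), clip_q = NULL)
  expect_equal(sc3$score, sc1$score)

  # gene order invariance
  sc4 <- score_module_spots(m2, c("g2", "g1"))
  expect_equal(sc4$score, sc2$score)

  # constant gene contributes 0
  m5 <- cbind(g1 = v, flat = rep(7, 5))
  rownames(m5) <- sprintf("s%d", 1:5)
  sc5 <- suppressMessages(score_module_spots(m5, c("g1", "flat")))
  expect_equal(sc5$score, sc$score / 2)
})

test_that("batch aggregates equal the mean of member spot scores", {
  sp <- small_spatial()$dataset
  norm <- senespat:::normalize_log1p(sp$counts)
  part <- structure(tibble::tibble(gene = colnames(norm)[1:10],
                                   module = "M1"),
                    class = c("module_partition", class(tibble::tibble())))
  sc <- score_modules(norm, part, sp$spot_meta)
  one <- sc$batch_scores[1, ]
  manual <- sc$spot_scores |>
    dplyr::left_join(sp$spot_meta, by = "spot_id") |>
    dplyr::filter(array_id == one$array_id, aar == one$aar)
  expect_equal(one$score, mean(manual$score))
})

test_that("Welch testing flags planted shifts and calibrates under the null", {
  set.seed(31)
  mk_scores <- function(shift_old = 0, n = 10) {
    tidyr::expand_grid(module = "M1", aar = c("L1", "WM"),
                       age_group = c("young", "old"),
                       rep = seq_len(n)) |>
      dplyr::mutate(
        array_id = paste0(age_group, rep),
        score = rnorm(dplyr::n()) +
          ifelse(age_group == "old", shift_old, 0))
  }
  # planted +1 SD shift in old arrays (n = 10/group): detected at q < 0.05
  # far above the 5% null rate (the single-instance power is ~50%, so the
  # check is phrased over replicates)
  hits <- 0L
  for (r in 1:60) {
    res <- test_scores_by_age(mk_scores(1),
                              comparisons = list(c("old", "young")))
    if (any(res$q.value < 0.05 & res$estimate > 0)) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.4)

  # identical distributions: across null replicates, families with any
  # BH discovery at q < 0.05 are ~5% or fewer
  n_fam_hit <- 0L
  n_rep <- 120
  for (r in seq_len(n_rep)) {
    res0 <- test_scores_by_age(mk_scores(0, n = 6),
                               comparisons = list(c("old", "young")))
    if (any(res0$q.value < 0.05)) n_fam_hit <- n_fam_hit + 1L
  }
  expect_lte(n_fam_hit / n_rep, 0.09)  # ~5% plus binomial noise

  # degenerate equal scores: t = 0, p = 1
  d <- tidyr::expand_grid(module = "M1", aar = "L1",
                          age_group = c("young", "old"), rep = 1:3) |>
    dplyr::mutate(array_id = paste0(age_group, rep), score = 1)
  r0 <- test_scores_by_age(d, comparisons = list(c("old", "young")))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  # group with < 2 arrays is skipped and recorded
  d2 <- mk_scores(0, n = 2) |> dplyr::filter(!(age_group == "old" & rep > 1))
  r2 <- test_scores_by_age(d2, comparisons = list(c("old", "young")))
  expect_true(all(r2$skipped))
})

test_that("a planted WM-enriched, age-increased module is discovered and
           flagged end to end", {
  cfg <- sim_config(
    n_donors_per_group = c(young = 6, old = 6), arrays_per_donor = 1,
    grid_shape = c(10, 10), n_genes = 260, theta = 0.1,
    baseline_log_rate = log(1),
    planted_modules = list(list(
      genes = 1:60,
      aar_effect = c(L1 = 0, L2 = 0, L3 = 0, L4 = 0, L5 = 0, L6 = 0,
                     WM = 1.5),
      group_effect = c(young = 0, old = 0.7))),
    spatial_sd = 0.15, noise_sd = 0.1, seed = 71
  )
  sim <- generate_spatial_dataset(cfg)
  ds <- sim$dataset
  norm <- senespat:::normalize_log1p(ds$counts)
  part <- graph_cluster(gene_correlation(norm), k = 10, resolution = 1,
                        min_size = 50, seed = 4)
  planted_genes <- sim$truth$modules$gene
  mods <- part$module[part$gene %in% planted_genes]
  # the planted genes land together in one retained module
  main <- names(sort(table(mods), decreasing = TRUE))[1]
  expect_false(is.na(main))
  expect_gte(mean(mods == main, na.rm = TRUE), 0.95)
  # and that module contains few bystander genes
  members <- part$gene[!is.na(part$module) & part$module == main]
  expect_gte(mean(members %in% planted_genes), 0.9)

  sc <- score_modules(norm, part, ds$spot_meta)
  # WM enrichment of the planted module's spot scores
  joined <- sc$spot_scores |>
    dplyr::filter(module == main) |>
    dplyr::left_join(ds$spot_meta, by = "spot_id")
  expect_gt(mean(joined$score[joined$aar == "WM"]),
            mean(joined$score[joined$aar != "WM"]))

  res <- test_scores_by_age(sc$batch_scores,
                            comparisons = list(c("old", "young")))
  hit <- res |> dplyr::filter(module == main)
  expect_true(any(hit$q.value < 0.05 & hit$estimate > 0))
  expect_gte(mean(hit$estimate > 0), 0.9)
})
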