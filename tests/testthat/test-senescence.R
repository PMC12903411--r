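# Hallmark module scoring, young-referenced positivity, CDKN2A trends.

sen_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_donors_per_group = c(young = 6, old = 6),
        n_genes = 2600, n_nuclei_per_donor = 130,
        cell_types = c("Ast", "Oli"), n_markers_per_type = 5,
        nuclei_depth = 2500,
        planted_senescence = list(
          cell_type = "Oli", fraction = c(young = 0, old = 0.25),
          genes = NULL, effect = 3),
        seed = 404
      )
      hs <- generate_hallmark_genesets(cfg)
      gm <- senespat:::gene_metadata(cfg)
      cfg$planted_senescence$genes <-
        match(hs$individual$arrest, gm$gene)
      out <- generate_nuclei_dataset(cfg)
      cache <<- list(nuclei = out$dataset, truth = out$truth, hs = hs)
    }
    cache
  }
})

test_that("module scores cancel for control-distributed sets and rank
           planted senescent nuclei highly", {
  fx <- sen_fixture()
  nuclei <- fx$nuclei
  hs <- fx$hs
  # a pseudo-set drawn from the control pool scores ~0 on average
  pool <- setdiff(hs$control_pool, hs$control_set)
  fake_set <- pool[1:40]
  sc0 <- nuclei_module_score(nuclei, fake_set, hs$control_set, seed = 3)
  expect_lt(abs(mean(sc0$score)), 0.02)

  # planted senescent nuclei score higher on the planted hallmark
  sc <- nuclei_module_score(nuclei, hs$individual$arrest, hs$control_set,
                            seed = 3)
  sen <- fx$truth$senescent[sc$nucleus_id]
  expect_gt(mean(sc$score[sen]), mean(sc$score[!sen]) + 0.05)

  # two-gene toy: score is exactly the normalised difference
  cnt <- matrix(c(20, 19980, 40, 19960), 2, 2, byrow = TRUE)
  colnames(cnt) <- c("setg", "ctrlg")
  nd <- manual_nuclei(cnt, donor_id = "d1", age = 40, age_group = "young")
  sc2 <- nuclei_module_score(nd, "setg", "ctrlg", n_bins = 2)
  norm <- senespat:::normalize_log1p(cnt)
  expect_equal(sc2$score, unname(norm[, 1] - norm[, 2]))

  # shared-set genes are rejected
  expect_error(nuclei_module_score(nuclei, fake_set,
                                   c(hs$control_set, fake_set[1])),
               "disjoint")
})

test_that("scores are invariant to a global depth rescaling", {
  fx <- sen_fixture()
  nuclei <- fx$nuclei
  hs <- fx$hs
  sc <- nuclei_module_score(nuclei, hs$individual$SASP, hs$control_set,
                            seed = 5)
  doubled <- nuclei
  doubled$counts <- nuclei$counts * 2
  sc2 <- nuclei_module_score(doubled, hs$individual$SASP, hs$control_set,
                             seed = 5)
  # 10k depth normalisation absorbs the rescaling exactly
  expect_equal(sc2$score, sc$score)
})

test_that("positivity thresholds implement the young top-5% rule", {
  # young scores 1..100: type-7 95th percentile = 95.05, 5 scores above
  d <- tibble::tibble(
    hallmark = "arrest", kind = "individual", cell_type = "Oli",
    age_group = "young", score = 1:100,
    nucleus_id = sprintf("n%03d", 1:100)
  )
  th <- positivity_thresholds(d)
  expect_equal(th$threshold, 95.05)
  expect_identical(sum(d$score > th$threshold), 5L)

  # all-equal young scores: threshold equals the constant, zero positives
  d2 <- d |> dplyr::mutate(score = 7)
  th2 <- positivity_thresholds(d2)
  expect_equal(th2$threshold, 7)
  expect_identical(sum(d2$score > th2$threshold), 0L)

  # large-sample normal check: threshold near qnorm(0.95)
  set.seed(11)
  d3 <- d[rep(1, 10000), ] |> dplyr::mutate(score = rnorm(10000))
  expect_lt(abs(positivity_thresholds(d3)$threshold - qnorm(0.95)), 0.05)

  # understaffed stratum: threshold undefined
  d4 <- d[1:10, ]
  expect_true(is.na(positivity_thresholds(d4)$threshold))
})

test_that("classification is strict and young positivity sits near 5%", {
  fx <- sen_fixture()
  scores <- score_hallmarks(fx$nuclei, fx$hs, seed = 9)
  th <- positivity_thresholds(scores)
  cls <- classify_positive(scores, th)

  # strictness: a nucleus exactly at threshold is negative
  row <- cls$table[!is.na(cls$table$threshold), ][1, ]
  fake <- row |> dplyr::mutate(score = threshold)
  expect_false((fake$score > fake$threshold))

  # by construction the young positivity rate per stratum is ~5%
  young_rate <- cls$table |>
    dplyr::filter(age_group == "young", !is.na(positive)) |>
    dplyr::group_by(hallmark, cell_type) |>
    dplyr::summarise(rate = mean(positive), .groups = "drop")
  expect_true(all(abs(young_rate$rate - 0.05) < 0.015))

  # 3+ flag counts individual hallmarks only
  expect_true(all(cls$summary$three_plus ==
                    (cls$summary$n_individual_positive >= 3)))
  burden_max <- max(cls$summary$n_individual_positive)
  expect_lte(burden_max, 7)
})

test_that("planted senescence raises old positivity for the planted
           hallmark specifically", {
  fx <- sen_fixture()
  scores <- score_hallmarks(fx$nuclei, fx$hs, seed = 9)
  th <- positivity_thresholds(scores)
  cls <- classify_positive(scores, th)
  rates <- cls$table |>
    dplyr::filter(cell_type == "Oli", kind == "individual",
                  !is.na(positive)) |>
    dplyr::group_by(hallmark, age_group) |>
    dplyr::summarise(rate = mean(positive), .groups = "drop") |>
    tidyr::pivot_wider(names_from = age_group, values_from = rate)
  planted <- rates |> dplyr::filter(hallmark == "arrest")
  expect_gt(planted$old, planted$young + 0.1)
  others <- rates |> dplyr::filter(hallmark != "arrest")
  # unplanted hallmarks: no comparable inflation (multi lists may share a
  # few planted genes; individual lists are disjoint from arrest)
  expect_true(all(others$old - others$young < 0.1))

  # the MASC-backed proportion test flags the planted hallmark
  tt <- test_positivity_by_age(cls, c("old", "young"))
  hit <- tt |> dplyr::filter(cell_type == "Oli", hallmark == "arrest")
  expect_true(hit$or > 2 || hit$separated)
  expect_lt(hit$p_masc, 0.01)
  expect_gt(hit$prop_stat, 0)
})

test_that("transcript positivity fractions and age trends are recovered", {
  # counts (0,1,3,0) -> 50% positive
  cnt <- matrix(c(0, 1, 3, 0), 4, 1, dimnames = list(NULL, "CDKN2A"))
  nd <- manual_nuclei(cnt, donor_id = "d1", age = 40, age_group = "young")
  pt <- cdkn2a_positivity(nd)
  expect_equal(pt$per_donor$pct_positive, 50)

  # exactly linear positivity in age -> R2 = 1
  ages <- c(30, 40, 50, 60, 70)
  blocks <- lapply(seq_along(ages), function(i) {
    pos <- round(ages[i] / 10)  # 3,4,5,6,7 positives of 10
    matrix(c(rep(1, pos), rep(0, 10 - pos)), 10, 1,
           dimnames = list(NULL, "CDKN2A"))
  })
  nd2 <- manual_nuclei(do.call(rbind, blocks),
                       donor_id = rep(sprintf("d%d", 1:5), each = 10),
                       age = rep(ages, each = 10), age_group = "young")
  pt2 <- cdkn2a_positivity(nd2)
  expect_equal(pt2$r2, 1)
  expect_equal(pt2$slope, 1)  # 10 pct points per 10 years

  # noisy linear trend: slope recovered within 2 SE
  set.seed(21)
  n_d <- 30
  ages3 <- round(seq(28, 88, length.out = n_d))
  frac <- 0.05 + 0.002 * ages3 + rnorm(n_d, 0, 0.01)
  blocks3 <- lapply(seq_len(n_d), function(i) {
    k <- round(100 * frac[i])
    matrix(c(rep(1, k), rep(0, 100 - k)), 100, 1,
           dimnames = list(NULL, "CDKN2A"))
  })
  nd3 <- manual_nuclei(do.call(rbind, blocks3),
                       donor_id = rep(sprintf("d%02d", 1:n_d), each = 100),
                       age = rep(ages3, each = 100), age_group = "young")
  pt3 <- cdkn2a_positivity(nd3)
  se <- summary(stats::lm(pct_positive ~ age,
                          data = pt3$per_donor))$coefficients["age", 2]
  expect_lt(abs(pt3$slope - 0.2), 2 * se)
  expect_equal(glance(pt3)$n_donors, n_d)
})

test_that("hallmark lists round-trip through plain-text files", {
  cfg <- sim_config(n_genes = 2600, seed = 5)
  hs <- generate_hallmark_genesets(cfg, multi_size = 12, hallmark_size = 8)
  dir <- withr::local_tempdir()
  write_hallmark_sets(hs, dir)
  back <- read_hallmark_sets(dir)
  # files come back in alphabetical order; contents must match exactly
  expect_identical(back$multi[sort(names(hs$multi))],
                   hs$multi[sort(names(hs$multi))])
  expect_identical(back$individual[sort(names(hs$individual))],
                   hs$individual[sort(names(hs$individual))])
  expect_identical(back$control_set, hs$control_set)

  # the shipped synthetic fixture parses and rebuilds its control set
  fx <- read_hallmark_sets(system.file("extdata", "hallmarks_synthetic",
                                       package = "senespat"))
  expect_length(fx$multi, 3)
  expect_length(fx$individual, 7)
  universe <- sprintf("G%05d", 1:2600)
  fx2 <- with_control_set(fx, universe, control_n = 500, seed = 2)
  expect_length(fx2$control_set, 500)
  expect_length(intersect(fx2$control_set,
                          unlist(c(fx2$multi, fx2$individual))), 0)
})
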