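# Spot graph, ZIP model parameter recovery, Savage-Dickey BF, DE calls.

test_that("spot graph counts rook edges within arrays only", {
  ds <- manual_spatial(matrix(1, 4, 1), row = c(1, 1, 2, 2),
                       col = c(1, 2, 1, 2))
  expect_identical(nrow(build_spot_graph(ds)$edges), 4L)

  ds9 <- manual_spatial(matrix(1, 9, 1), row = rep(1:3, each = 3),
                        col = rep(1:3, times = 3))
  expect_identical(nrow(build_spot_graph(ds9)$edges), 12L)

  ds2 <- manual_spatial(matrix(1, 4, 1), row = c(1, 1, 1, 1),
                        col = c(1, 2, 1, 2),
                        array_id = c("a1", "a1", "a2", "a2"))
  g2 <- build_spot_graph(ds2)
  expect_identical(nrow(g2$edges), 2L)
  expect_true(all(g2$array_id[g2$edges[, 1]] == g2$array_id[g2$edges[, 2]]))

  dup <- manual_spatial(matrix(1, 2, 1), row = c(1, 1), col = c(1, 1))
  expect_error(build_spot_graph(dup), "duplicate")
})

test_that("Savage-Dickey BF matches closed-form conjugate cases", {
  set.seed(42)
  # posterior equal to prior: no evidence either way
  expect_lt(abs(savage_dickey_bf(rnorm(20000, 0, 1), 1) - 1), 0.1)

  # prior N(0,1), posterior N(1, 0.5): BF = phi(0;0,1) / phi(0;1,0.5)
  target <- dnorm(0, 0, 1) / dnorm(0, 1, 0.5)
  bf <- savage_dickey_bf(rnorm(50000, 1, 0.5), 1)
  expect_lt(abs(bf - target) / target, 0.05)

  # overwhelming evidence hits the upper clip
  expect_identical(savage_dickey_bf(rnorm(1000, 5, 0.5), 1), 1e6)

  expect_error(savage_dickey_bf(rnorm(100), 1), "500")

  # monotone in |posterior mean| at fixed posterior sd
  bfs <- vapply(c(0.2, 0.5, 1, 1.5),
                function(m) savage_dickey_bf(rnorm(5000, m, 0.4), 1),
                numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("posterior mean beta recovers a known rate (one AAR, one group)", {
  bt <- flat_beta(1, 2, "young")
  cfg <- sim_config(n_donors_per_group = c(young = 9), arrays_per_donor = 1,
                    grid_shape = c(24, 24),
                    aar_band_rows = one_aar_bands(24), n_genes = 1,
                    theta = 0, spatial_sd = 0, noise_sd = 0,
                    beta_table = bt, frac_mito = 0, frac_lnc = 0,
                    frac_pseudo = 0, seed = 21)
  ds <- generate_spatial_dataset(cfg)$dataset
  expect_gte(nrow(ds$counts), 5000)
  fit <- fit_gene_model(ds, "G00001", backend = "mcmc",
                        spatial = FALSE, spot_noise = FALSE,
                        draws = 600, warmup = 600, seed = 4)
  expect_lt(abs(fit$beta_mean["L1", "young"] - 2), 0.05)
  # closed-form check: with a flat-ish prior the posterior of exp(beta) is
  # approximately Gamma(sum y, n); compare means on the log scale
  y <- as.numeric(ds$counts[, 1])
  expect_lt(abs(fit$beta_mean["L1", "young"] - log(mean(y))), 0.02)
})

test_that("all-zero counts keep theta near 1 without crashing", {
  cfg <- sim_config(n_donors_per_group = c(young = 1), grid_shape = c(8, 8),
                    aar_band_rows = one_aar_bands(8), n_genes = 1, theta = 1,
                    beta_table = flat_beta(1, log(2), "young"),
                    frac_mito = 0, frac_lnc = 0, frac_pseudo = 0, seed = 3)
  ds <- generate_spatial_dataset(cfg)$dataset
  fit <- suppressWarnings(
    fit_gene_model(ds, "G00001", backend = "mcmc", spatial = FALSE,
                   spot_noise = FALSE, draws = 400, warmup = 400, seed = 2))
  # theta and lambda are not jointly identified on all-zero data: lambda
  # collapses toward its prior floor and theta stays diffuse over the
  # dropout explanation (upper quantiles well above the prior mean)
  expect_lt(mean(fit$lambda_mean), 0.5)
  expect_lt(mean(fit$beta_draws[, "L1", "young"]), 0)
  expect_gt(quantile(fit$theta_draws, 0.9), 0.5)
})

test_that("group difference is recovered at the MEDIUM design", {
  # two groups, true delta-beta = ln 2 at 0.6 counts/spot, 20 arrays/group
  bt <- flat_beta(1, log(0.6))
  bt[1, , "old"] <- bt[1, , "old"] + log(2)
  cfg <- sim_config(n_donors_per_group = c(young = 20, old = 20),
                    arrays_per_donor = 1, grid_shape = c(15, 15),
                    n_genes = 1, theta = 0.1, beta_table = bt,
                    spatial_sd = 0, noise_sd = 0,
                    frac_mito = 0, frac_lnc = 0, frac_pseudo = 0, seed = 31)
  ds <- generate_spatial_dataset(cfg)$dataset
  fit <- fit_gene_model(ds, "G00001", backend = "vi", draws = 1000, seed = 8)
  delta <- mean(fit$beta_draws[, , "old"] - fit$beta_draws[, , "young"])
  expect_lt(abs(delta - log(2)), 0.15)
})

test_that("run_de applies the BF and fold-change gates with tiers", {
  # synthetic posterior draws with controlled means
  mk_fit <- function(delta_l2, sd = 0.02) {
    dr <- array(0, c(2000, 1, 2), dimnames = list(NULL, "L1",
                                                  c("young", "old")))
    dr[, 1, "old"] <- rnorm(2000, delta_l2 * log(2), sd)
    structure(list(gene = "g", beta_draws = dr, aars = "L1",
                   groups = c("young", "old"), sigma_beta = 0.5),
              class = "zip_spatial_fit")
  }
  set.seed(9)
  de_big <- run_de(mk_fit(1.5), c("old", "young"))
  expect_true(de_big$significant)
  expect_true(de_big$tier %in% c("*", "**", "***"))

  # strong BF but small fold change: gated out
  de_small <- run_de(mk_fit(0.2, sd = 0.005), c("old", "young"))
  expect_gt(de_small$bf, 30)
  expect_false(de_small$significant)

  expect_error(run_de(mk_fit(1), c("old", "middle")), "absent")
})

test_that("DE screen has power on planted signals and holds its size", {
  # 25 null + 8 planted log2FC = 2 genes at HIGH expression
  n_null <- 25; n_sig <- 8
  bt <- flat_beta(n_null + n_sig, log(10))
  bt[seq_len(n_sig), , "old"] <- bt[seq_len(n_sig), , "old"] + 2 * log(2)
  cfg <- sim_config(n_donors_per_group = c(young = 4, old = 4),
                    arrays_per_donor = 1, grid_shape = c(14, 14),
                    n_genes = n_null + n_sig, theta = 0.1, beta_table = bt,
                    spatial_sd = 0, noise_sd = 0, frac_mito = 0,
                    frac_lnc = 0, frac_pseudo = 0, seed = 77)
  ds <- generate_spatial_dataset(cfg)$dataset
  fits <- lapply(colnames(ds$counts), function(g) {
    fit_gene_model(ds, g, backend = "vi", draws = 800, seed = 5)
  })
  de <- run_de(fits, c("old", "young"))
  calls <- de |>
    dplyr::group_by(gene) |>
    dplyr::summarise(hit = any(significant))
  planted <- sprintf("G%05d", seq_len(n_sig))
  expect_gte(sum(calls$hit[calls$gene %in% planted]), n_sig - 1)
  expect_lte(sum(calls$hit[!calls$gene %in% planted]), 2)
})

test_that("credible intervals cover the truth across a gene screen", {
  # 50 genes whose true betas are drawn from the model's own prior;
  # 90% intervals should cover at >= 85%
  set.seed(123)
  n_genes <- 50
  mu_true <- rnorm(7, log(0.8), 0.5)
  bt <- array(rnorm(n_genes * 7 * 2,
                    rep(mu_true, each = n_genes), 0.5),
              dim = c(n_genes, 7, 2),
              dimnames = list(NULL, c("L1", "L2", "L3", "L4", "L5", "L6",
                                      "WM"), c("young", "old")))
  cfg <- sim_config(n_donors_per_group = c(young = 3, old = 3),
                    arrays_per_donor = 1, grid_shape = c(14, 14),
                    n_genes = n_genes, theta = 0.1, beta_table = bt,
                    spatial_sd = 0, noise_sd = 0, frac_mito = 0,
                    frac_lnc = 0, frac_pseudo = 0, seed = 88)
  ds <- generate_spatial_dataset(cfg)$dataset
  covered <- 0L; total <- 0L
  for (i in seq_len(n_genes)) {
    fit <- fit_gene_model(ds, sprintf("G%05d", i), backend = "vi",
                          draws = 800, seed = i)
    td <- tidy(fit, conf_level = 0.90)
    truth <- c(bt[i, , "young"], bt[i, , "old"])[
      paste(td$aar, td$group) |> match(
        paste(rep(c("L1", "L2", "L3", "L4", "L5", "L6", "WM"), 2),
              rep(c("young", "old"), each = 7)))]
    covered <- covered + sum(td$conf.low <= truth & truth <= td$conf.high)
    total <- total + nrow(td)
  }
  expect_gte(covered / total, 0.85)
})
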