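null_modules <- tibble::tibble(size = integer(), rho = numeric(),
                               is_meiotic = logical())

test_that("transcriptome generation is a pure function of (config, seed)", {
  cfg <- sim_config(n_genes = 200, n_samples = 30, n_wgd_samples = 10,
                    gg_fraction = 0.2,
                    module_spec = tibble::tibble(size = 10L, rho = 0.7,
                                                 is_meiotic = TRUE))
  a <- simulate_transcriptome(cfg, seed = 2)
  b <- simulate_transcriptome(cfg, seed = 2)
  expect_identical(a$mat, b$mat)
  expect_identical(a$de, b$de)
  expect_identical(a$ploidy, b$ploidy)
  c <- simulate_transcriptome(cfg, seed = 3)
  expect_false(identical(a$mat, c$mat))
})

test_that("a null configuration plants nothing", {
  cfg <- sim_config(n_genes = 150, n_samples = 20, n_wgd_samples = 10,
                    gg_up_rate_wgd = 0, base_up_rate = 0,
                    gg_down_rate = 0, base_down_rate = 0,
                    module_spec = null_modules)
  sim <- simulate_transcriptome(cfg, seed = 8)
  expect_true(all(sim$truth$genes$direction == "none"))
  expect_true(all(abs(sim$de$logFC) < 0.5))
  expect_true(all(sim$de$pAdj >= 0.05))
})

test_that("config validation rejects impossible cohorts", {
  expect_error(sim_config(n_samples = 10, n_wgd_samples = 11), "exceeds")
  expect_error(proteome_sim_config(block_sizes = c(10, 10), n_samples = 30))
  expect_error(sim_config(rho_between = 0.8), "rho_between")
})

test_that("planted modules reach their nominal within-module correlation", {
  cfg <- sim_config(n_genes = 400, n_samples = 100, n_wgd_samples = 40,
                    module_spec = tibble::tibble(size = 15L, rho = 0.8,
                                                 is_meiotic = TRUE),
                    rho_between = 0)
  sim <- simulate_transcriptome(cfg, seed = 13)
  rows <- which(!is.na(sim$truth$genes$module))
  corr <- pairwise_pearson(sim$mat[rows, ])
  mean_r <- mean(corr[upper.tri(corr)])
  expect_gt(mean_r, 0.7)
  expect_lt(mean_r, 0.9)
})

test_that("between-module correlation approximates rho_between", {
  cfg <- sim_config(n_genes = 500, n_samples = 200, n_wgd_samples = 50,
                    module_spec = tibble::tibble(size = c(15L, 15L),
                                                 rho = c(0.75, 0.75),
                                                 is_meiotic = c(TRUE, TRUE)),
                    rho_between = 0.5, gg_fraction = 0.2)
  sim <- simulate_transcriptome(cfg, seed = 19)
  truth <- sim$truth$genes
  m1 <- which(truth$module == 1)
  m2 <- which(truth$module == 2)
  corr <- pairwise_pearson(sim$mat[c(m1, m2), ])
  between <- corr[seq_along(m1), length(m1) + seq_along(m2)]
  expect_equal(mean(between), 0.5, tolerance = 0.15)
})

test_that("the WGD shift moves planted genes by their tabulated logFC", {
  cfg <- sim_config(n_genes = 300, n_samples = 400, n_wgd_samples = 200,
                    module_spec = null_modules, logfc_effect_size = 2)
  sim <- simulate_transcriptome(cfg, seed = 31)
  truth <- sim$truth$genes
  up <- which(truth$direction == "up")[1:5]
  wgd <- sim$ploidy$wgd
  for (g in up) {
    observed <- mean(sim$mat[g, wgd]) - mean(sim$mat[g, !wgd])
    expect_equal(observed, sim$de$logFC[g], tolerance = 0.35)
  }
})

test_that("proteome missingness hits the configured marginal rate", {
  cfg <- proteome_sim_config(n_proteins = 600, n_samples = 120,
                             block_sizes = c(60, 60), block_shift = c(0, 3),
                             missing_rate = 0.35,
                             module_spec = tibble::tibble(size = integer(),
                                                          rho = numeric()))
  sim <- simulate_proteome(cfg, seed = 6)
  expect_equal(mean(is.na(sim$mat)), 0.35, tolerance = 0.05)

  none <- proteome_sim_config(n_proteins = 100, n_samples = 20,
                              block_sizes = c(10, 10), block_shift = c(0, 2),
                              missing_rate = 0,
                              module_spec = tibble::tibble(size = integer(),
                                                           rho = numeric()))
  expect_false(anyNA(simulate_proteome(none, seed = 1)$mat))
})

test_that("missingness is enriched at low abundance (MNAR)", {
  cfg <- proteome_sim_config(n_proteins = 800, n_samples = 60,
                             block_sizes = c(30, 30), block_shift = c(0, 0),
                             missing_rate = 0.3, block_signature_fraction = 0,
                             module_spec = tibble::tibble(size = integer(),
                                                          rho = numeric()))
  sim <- simulate_proteome(cfg, seed = 9)
  row_miss <- rowMeans(is.na(sim$mat))
  row_mean <- rowMeans(sim$mat, na.rm = TRUE)
  ok <- !is.nan(row_mean)
  expect_lt(cor(row_mean[ok], row_miss[ok]), -0.5)
})

test_that("proteome generation is deterministic and proteoforms map back", {
  cfg <- proteome_sim_config(n_proteins = 200, n_samples = 24,
                             block_sizes = c(12, 12), block_shift = c(0, 2),
                             module_spec = tibble::tibble(size = integer(),
                                                          rho = numeric()))
  a <- simulate_proteome(cfg, seed = 4)
  b <- simulate_proteome(cfg, seed = 4)
  expect_identical(a$mat, b$mat)
  expect_equal(proteoform_to_symbol(a$truth$proteins$protein),
               a$truth$proteins$gene)
})

test_that("planted sample blocks are recoverable by the tree cut", {
  cfg <- proteome_sim_config(n_proteins = 2000, n_samples = 150,
                             block_sizes = c(40, 60, 50),
                             block_shift = c(0, 2, -2),
                             module_spec = tibble::tibble(size = rep(20L, 3),
                                                          rho = rep(0.7, 3)))
  sim <- simulate_proteome(cfg, seed = 3)
  cl <- cluster_samples(sim$mat, cut_height = 0)
  labels <- cluster_samples(sim$mat,
                            cut_height = cut_height_for_k(cl, 3))$clusters
  joined <- dplyr::inner_join(labels, sim$truth$samples, by = "sample")
  expect_gte(ari(joined$cluster, joined$block), 0.9)
})
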