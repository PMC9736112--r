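test_that("fraction-of-samples bounds match the worked arithmetic", {
  expect_equal(min_samples_required(505, 0.2), 101L)
  expect_equal(min_samples_required(142, 0.2), 29L)
  expect_equal(min_samples_required(10, 1), 10L)
})

test_that("low-expression filtering is inclusive at the boundary", {
  mat <- matrix(0, 5, 5, dimnames = list(paste0("g", 1:5), paste0("s", 1:5)))
  mat["g1", ] <- 10                       # clearly expressed
  mat["g2", 1] <- 2                       # exactly min_value in exactly
  # ceiling(0.2 * 5) = 1 sample: kept
  mat["g3", 1] <- 1.99
  mat["g4", 1] <- NA                      # missing counts as below
  out <- low_expression_filter(mat, min_value = 2, min_fraction = 0.2)
  expect_setequal(rownames(out), c("g1", "g2"))
  expect_error(low_expression_filter(matrix(nrow = 0, ncol = 0)), "non-empty")
})

test_that("WGD stratification applies the strict purity cutoff", {
  mat <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  calls <- tibble::tibble(
    sample = paste0("s", 1:10),
    wgd = rep(c(TRUE, FALSE), 5),
    purity = c(0.5, 0.5, rep(0.9, 8))     # two samples at exactly 0.5
  )
  out <- stratify_by_wgd(mat, calls, min_wgd_samples = 2, min_up_genes = 1,
                         up_genes = c("g1", "g2"))
  expect_equal(ncol(out$wgd_plus) + ncol(out$wgd_minus), 8)
  expect_false("s1" %in% c(colnames(out$wgd_plus), colnames(out$wgd_minus)))
  expect_equal(out$eligibility$n_wgd_plus, 4)
  expect_true(out$eligibility$eligible)

  expect_error(stratify_by_wgd(mat, calls[1:5, ]), "without a ploidy call")
  calls_all_wgd <- dplyr::mutate(calls, wgd = TRUE, purity = 1)
  expect_warning(stratify_by_wgd(mat, calls_all_wgd), "no WGD-")
})

test_that("eligibility matches a hand count on a planted cohort", {
  sim <- simulate_transcriptome(sim_config(n_genes = 50, n_samples = 150,
                                           n_wgd_samples = 60,
                                           module_spec = tibble::tibble(
                                             size = integer(), rho = numeric(),
                                             is_meiotic = logical())),
                                seed = 4)
  out <- stratify_by_wgd(sim$mat, sim$ploidy, min_wgd_samples = 40)
  hand <- sum(sim$ploidy$wgd & sim$ploidy$purity > 0.5)
  expect_equal(out$eligibility$n_wgd_plus, hand)
  expect_equal(out$eligibility$eligible, hand >= 40)
})

test_that("pairwise correlations match hand-computed values", {
  x <- c(1, 2, 3, 4)
  mat <- rbind(a = x, b = -x, c = c(2, 1, 4, 3))
  corr <- pairwise_pearson(mat)
  expect_equal(diag(corr), c(a = 1, b = 1, c = 1))
  expect_equal(corr["a", "b"], -1)
  hand_ac <- sum((x - mean(x)) * (mat["c", ] - mean(mat["c", ]))) /
    (sqrt(sum((x - mean(x))^2)) * sqrt(sum((mat["c", ] - mean(mat["c", ]))^2)))
  expect_equal(corr["a", "c"], hand_ac)
  expect_error(pairwise_pearson(mat[, 1:2]), "3 samples")
  expect_error(pairwise_pearson(rbind(mat, d = c(NA, 1, 2, 3))), "missing")
})

test_that("constant genes correlate as zero and are flagged", {
  mat <- rbind(a = c(1, 2, 3, 4), flat = c(5, 5, 5, 5))
  corr <- pairwise_pearson(mat)
  expect_equal(corr["a", "flat"], 0)
  expect_equal(diag(corr), c(a = 1, flat = 1))
  expect_equal(attr(corr, "constant_genes"), "flat")
})

test_that("surrogate permutation preserves each row's multiset of values", {
  set.seed(31)
  mat <- matrix(rnorm(15 * 8), 15, 8)
  shuf <- permute_rows_cpp(mat)
  for (i in seq_len(nrow(mat))) {
    expect_equal(sort(shuf[i, ]), sort(mat[i, ]))
  }
  expect_false(identical(shuf, mat))
})

test_that("calibration picks 0.6 on planted modules and none on noise", {
  sim <- simulate_module_matrix(seed = 7)
  cal <- calibrate_threshold(sim$mat, seed = 7)
  expect_equal(cal$chosen_threshold, 0.6)
  expect_true(all(cal$summary$median_real[1:2] >
                    cal$summary$median_surrogate[1:2]))

  set.seed(8)
  noise <- matrix(rnorm(1000 * 100), 1000, 100)
  cal0 <- calibrate_threshold(noise, seed = 8)
  expect_true(is.na(cal0$chosen_threshold))
})

test_that("perfectly collinear genes pass every candidate, smallest chosen", {
  set.seed(2)
  base <- rnorm(50)
  mat <- t(vapply(seq_len(320), function(i) i * base, numeric(50)))
  rownames(mat) <- paste0("g", seq_len(320))
  expect_warning(cal <- calibrate_threshold(mat, n_sets = 5, set_size = 300,
                                            n_shuffles = 10, seed = 2),
                 NA)
  expect_true(all(cal$summary$pass))
  expect_equal(cal$chosen_threshold, 0.6)
})

test_that("calibration handles degenerate and undersized matrices", {
  flat <- matrix(1, 10, 10)
  expect_warning(cal <- calibrate_threshold(flat, n_sets = 2, set_size = 5,
                                            n_shuffles = 2),
                 "degenerate")
  expect_true(is.na(cal$chosen_threshold))

  sim <- simulate_module_matrix(n_modules = 2, module_size = 10, n_noise = 20,
                                n_samples = 30, seed = 1)
  expect_warning(cal2 <- calibrate_threshold(sim$mat, n_sets = 3,
                                             set_size = 300, n_shuffles = 3,
                                             seed = 1),
                 "set_size")
  expect_equal(cal2$config$set_size, nrow(sim$mat))
})

test_that("calibration is bit-reproducible under a fixed seed", {
  sim <- simulate_module_matrix(n_modules = 5, module_size = 10, n_noise = 50,
                                n_samples = 40, seed = 3)
  a <- calibrate_threshold(sim$mat, n_sets = 5, set_size = 50,
                           n_shuffles = 10, seed = 11)
  b <- calibrate_threshold(sim$mat, n_sets = 5, set_size = 50,
                           n_shuffles = 10, seed = 11)
  expect_identical(a$real_counts, b$real_counts)
  expect_identical(a$surrogate_counts, b$surrogate_counts)
  expect_identical(a$chosen_threshold, b$chosen_threshold)
})

test_that("graphs are unsigned, simple, inclusive at the threshold", {
  corr <- diag(4)
  dimnames(corr) <- list(letters[1:4], letters[1:4])
  corr["a", "b"] <- corr["b", "a"] <- 0.7
  corr["a", "c"] <- corr["c", "a"] <- -0.7
  corr["b", "c"] <- corr["c", "b"] <- 0.3
  corr["a", "d"] <- corr["d", "a"] <- 0.6   # boundary: included
  g <- build_graph(corr, 0.6)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(igraph::vcount(g), 4)
  expect_false(igraph::any_loop(g))
  r <- igraph::E(g)$r
  expect_true(all(abs(r) >= 0.6))
  expect_true(any(r < 0))

  g1 <- build_graph(corr, 1)
  expect_equal(igraph::ecount(g1), 0)      # only exact +/-1 off-diagonal
})

test_that("edge counts are non-increasing in the threshold", {
  sim <- simulate_module_matrix(n_modules = 4, module_size = 10, n_noise = 30,
                                n_samples = 50, seed = 6)
  corr <- pairwise_pearson(sim$mat)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9),
                   function(t) igraph::ecount(build_graph(corr, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted modules are far denser inside than between", {
  sim <- simulate_module_matrix(n_modules = 4, module_size = 15, n_noise = 0,
                                n_samples = 100, seed = 12)
  g <- build_graph(pairwise_pearson(sim$mat), 0.6)
  el <- igraph::as_edgelist(g)
  mod <- sim$truth$module[match(el[, 1], sim$truth$gene)]
  mod2 <- sim$truth$module[match(el[, 2], sim$truth$gene)]
  n_within <- sum(mod == mod2)
  n_between <- sum(mod != mod2)
  within_pairs <- 4 * choose(15, 2)
  between_pairs <- choose(60, 2) - within_pairs
  expect_gt((n_within / within_pairs) / max(n_between / between_pairs, 1e-6),
            10)
})
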