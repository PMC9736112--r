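#' Configuration for a synthetic WGD transcriptome cohort
#'
#' Defaults emulate a large TCGA-style cohort: 2000 profiled genes, 500
#' samples of which 220 (44%) carry a whole-genome duplication, tumour purity
#' uniform on (0.3, 1), a GG (gametogenesis-related) fraction of 7.5% of the
#' gene universe, GG genes ploidy-upregulated at three times the background
#' rate (0.21 vs 0.07), and GG genes depleted among downregulated genes
#' (0.01 vs 0.07). Planted coexpression modules are built from a shared
#' latent factor per module (`x = sqrt(rho) * f + sqrt(1 - rho) * e`), giving
#' expected within-module Pearson correlation `rho`; module members are
#' always planted as ploidy-upregulated, and "meiotic" modules are carved
#' from GG genes. Phylostratum labels are drawn per gene: the GG distribution
#' peaks at stratum 2 (Eukaryota) and 8 (Euteleostomi) with secondary mass in
#' strata 12 and 14 (placental mammals, Catarrhini), against a broad old-gene
#' background.
#'
#' @param n_genes,n_samples,n_wgd_samples Cohort dimensions.
#' @param gg_fraction Fraction of genes flagged GG.
#' @param gg_up_rate_wgd,base_up_rate Planted upregulation probabilities for
#'   GG and non-GG genes.
#' @param gg_down_rate,base_down_rate Planted downregulation probabilities.
#' @param logfc_effect_size Mean absolute log2 fold-change of planted genes.
#' @param module_spec Data frame with columns `size`, `rho`, `is_meiotic`
#'   describing planted coexpression modules.
#' @param rho_between Expected correlation between genes of *different*
#'   modules (module factors share a global factor), so the planted modules
#'   connect into one giant component as observed coexpression networks do;
#'   must be smaller than every within-module `rho`. Set 0 for independent
#'   modules.
#' @param noise_sd Residual standard deviation of expression.
#' @param purity_min,purity_max Uniform purity bounds.
#' @param annot_coverage Fraction of genes with a phylostratum label.
#' @param gg_strata_probs,bg_strata_probs Length-16 stratum weight vectors.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_samples = 500, n_wgd_samples = 220,
                       gg_fraction = 0.075,
                       gg_up_rate_wgd = 0.21, base_up_rate = 0.07,
                       gg_down_rate = 0.01, base_down_rate = 0.07,
                       logfc_effect_size = 1,
                       module_spec = tibble::tibble(
                         size = rep(15L, 6),
                         rho = rep(0.75, 6),
                         is_meiotic = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
                       ),
                       rho_between = 0.5,
                       noise_sd = 1,
                       purity_min = 0.3, purity_max = 1,
                       annot_coverage = 0.9,
                       gg_strata_probs = c(6, 20, 7, 6, 6, 4, 4, 12,
                                           3, 3, 3, 8, 3, 8, 2, 1) / 96,
                       bg_strata_probs = c(10, 18, 8, 7, 6, 5, 5, 7,
                                           4, 4, 4, 5, 3, 4, 3, 2) / 95) {
  rates <- c(gg_fraction, gg_up_rate_wgd, base_up_rate, gg_down_rate,
             base_down_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            n_genes >= 1, n_samples >= 2,
            logfc_effect_size >= 0, noise_sd > 0,
            purity_min >= 0, purity_max <= 1, purity_min < purity_max,
            length(gg_strata_probs) == 16, length(bg_strata_probs) == 16)
  if (n_wgd_samples > n_samples) {
    stop("n_wgd_samples exceeds n_samples", call. = FALSE)
  }
  module_spec <- tibble::as_tibble(module_spec)
  if (nrow(module_spec) > 0) {
    stopifnot(all(c("size", "rho", "is_meiotic") %in% names(module_spec)),
              all(module_spec$rho > -1 & module_spec$rho < 1),
              all(module_spec$size >= 2),
              rho_between >= 0, all(rho_between < module_spec$rho))
  }
  structure(
    list(n_genes = n_genes, n_samples = n_samples,
         n_wgd_samples = n_wgd_samples, gg_fraction = gg_fraction,
         gg_up_rate_wgd = gg_up_rate_wgd, base_up_rate = base_up_rate,
         gg_down_rate = gg_down_rate, base_down_rate = base_down_rate,
         logfc_effect_size = logfc_effect_size, module_spec = module_spec,
         rho_between = rho_between,
         noise_sd = noise_sd, purity_min = purity_min,
         purity_max = purity_max, annot_coverage = annot_coverage,
         gg_strata_probs = gg_strata_probs, bg_strata_probs = bg_strata_probs),
    class = "sim_config"
  )
}

#' Simulate a WGD-stratified transcriptome cohort
#'
#' Generates an expression matrix (log2 TPM-like scale, genes x samples),
#' per-sample ploidy calls, a differential-expression table, and the planted
#' ground truth. The DE table is analytic — planted-up genes receive
#' `logFC > 0.5` and `pAdj < 0.05` by construction, planted-down genes the
#' mirror image, and unplanted genes `|logFC| < 0.5` — so downstream filter
#' tests have exact truth. WGD+ samples receive the planted log-fold-change
#' as a shift on the corresponding genes.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(cfg, seed)`.
#' @return A list of class `sim_transcriptome` with elements `mat`, `ploidy`,
#'   `de`, `truth` (lists `genes` and `samples`), and `config`.
#' @export
simulate_transcriptome <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n_g <- cfg$n_genes
  n_s <- cfg$n_samples
  genes <- sprintf("G%04d", seq_len(n_g))
  samples <- sprintf("S%04d", seq_len(n_s))

  # Bernoulli assignment at the configured rate (not a fixed count), so the
  # null model of the enrichment test matches its binomial assumptions
  is_gg <- stats::runif(n_g) < cfg$gg_fraction

  # planted modules: meiotic modules from GG genes, others from non-GG
  module <- rep(NA_integer_, n_g)
  ms <- cfg$module_spec
  if (nrow(ms) > 0) {
    pool_gg <- sample(which(is_gg))
    pool_bg <- sample(which(!is_gg))
    for (m in seq_len(nrow(ms))) {
      pool <- if (ms$is_meiotic[m]) pool_gg else pool_bg
      pool <- pool[is.na(module[pool])]
      if (length(pool) < ms$size[m]) {
        stop("not enough ", if (ms$is_meiotic[m]) "GG" else "background",
             " genes for module ", m, call. = FALSE)
      }
      module[pool[seq_len(ms$size[m])]] <- m
    }
  }

  # planted DE direction; module members are always ploidy-upregulated
  p_up <- ifelse(is_gg, cfg$gg_up_rate_wgd, cfg$base_up_rate)
  p_down <- ifelse(is_gg, cfg$gg_down_rate, cfg$base_down_rate)
  u <- stats::runif(n_g)
  direction <- ifelse(u < p_up, "up",
                      ifelse(u < p_up + p_down, "down", "none"))
  direction[!is.na(module)] <- "up"

  # analytic DE table (exact truth for the strict < / > filter)
  logfc <- numeric(n_g)
  padj <- numeric(n_g)
  planted <- direction != "none"
  sgn <- ifelse(direction == "up", 1, -1)
  logfc[planted] <- sgn[planted] *
    pmax(0.51, stats::rnorm(sum(planted), cfg$logfc_effect_size, 0.25))
  logfc[!planted] <- pmin(pmax(stats::rnorm(sum(!planted), 0, 0.2),
                               -0.49), 0.49)
  padj[planted] <- stats::runif(sum(planted), 1e-8, 0.049)
  padj[!planted] <- stats::runif(sum(!planted), 0.05, 1)

  # phylostrata
  stratum <- ifelse(
    is_gg,
    sample.int(16, n_g, replace = TRUE, prob = cfg$gg_strata_probs),
    sample.int(16, n_g, replace = TRUE, prob = cfg$bg_strata_probs)
  )
  stratum[stats::runif(n_g) > cfg$annot_coverage] <- NA_integer_

  # samples
  wgd <- seq_len(n_s) %in% sample.int(n_s, cfg$n_wgd_samples)
  purity <- stats::runif(n_s, cfg$purity_min, cfg$purity_max)
  ploidy <- ifelse(wgd, 4, 2) + stats::rnorm(n_s, 0, 0.15)

  # expression: baseline + module latent factor + noise + WGD shift
  baseline <- stats::runif(n_g, 0, 8)
  baseline[!is.na(module)] <- stats::runif(sum(!is.na(module)), 5, 8)
  mat <- baseline + cfg$noise_sd * matrix(stats::rnorm(n_g * n_s), n_g, n_s)
  if (nrow(ms) > 0) {
    factors <- module_factors(ms$rho, cfg$rho_between, n_s)
    for (m in seq_len(nrow(ms))) {
      rows <- which(module == m)
      rho <- ms$rho[m]
      eps <- matrix(stats::rnorm(length(rows) * n_s), length(rows), n_s)
      mat[rows, ] <- baseline[rows] + cfg$noise_sd *
        (sqrt(rho) * matrix(factors[m, ], length(rows), n_s, byrow = TRUE) +
           sqrt(1 - rho) * eps)
    }
  }
  mat[planted, wgd] <- mat[planted, wgd] + logfc[planted]
  dimnames(mat) <- list(genes, samples)

  structure(
    list(
      mat = mat,
      ploidy = tibble::tibble(sample = samples, wgd = wgd,
                              purity = purity, ploidy = ploidy),
      de = tibble::tibble(gene = genes, logFC = logfc, pAdj = padj),
      truth = list(
        genes = tibble::tibble(
          gene = genes, is_gg = is_gg, direction = direction,
          module = module, stratum = stratum
        ),
        samples = tibble::tibble(sample = samples, wgd = wgd, purity = purity)
      ),
      config = cfg
    ),
    class = "sim_transcriptome"
  )
}

# Module latent factors sharing a global factor: between-module gene
# correlation equals rho_between (for modules with equal within-rho), since
# cor(x_i, x_j) = sqrt(rho_m * rho_m') * cor(f_m, f_m').
module_factors <- function(rho, rho_between, n_samples) {
  n_mod <- length(rho)
  u <- matrix(stats::rnorm(n_mod * n_samples), n_mod, n_samples)
  if (rho_between <= 0 || n_mod < 2) return(u)
  g <- stats::rnorm(n_samples)
  k <- rho_between / rho
  sqrt(k) * matrix(g, n_mod, n_samples, byrow = TRUE) + sqrt(1 - k) * u
}

#' Phylostratum annotation table of a simulated cohort
#'
#' @param sim A `sim_transcriptome`.
#' @return Tibble (`gene`, `phylostratum`) restricted to annotated genes.
#' @export
sim_phylo_annotation <- function(sim) {
  g <- sim$truth$genes
  tibble::tibble(gene = g$gene, phylostratum = g$stratum) |>
    dplyr::filter(!is.na(.data$phylostratum))
}

#' Simulate a planted-module expression matrix
#'
#' The workhorse fixture for threshold calibration and MCL recovery:
#' `n_modules` modules of `module_size` genes sharing a latent factor
#' (within-module correlation `rho` in expectation) plus `n_noise`
#' uncorrelated genes, all with unit residual noise.
#'
#' @param n_modules Number of planted modules (default 20).
#' @param module_size Genes per module (default 15).
#' @param rho Within-module correlation (default 0.75).
#' @param n_noise Uncorrelated genes (default 300).
#' @param n_samples Samples (default 100).
#' @param seed Integer seed.
#' @return List with `mat` (genes x samples) and `truth` (tibble `gene`,
#'   `module`; `NA` module for noise genes).
#' @export
simulate_module_matrix <- function(n_modules = 20, module_size = 15,
                                   rho = 0.75, n_noise = 300,
                                   n_samples = 100, seed = 1) {
  stopifnot(rho > -1, rho < 1, n_samples >= 3)
  set.seed(seed)
  n_mod_genes <- n_modules * module_size
  n_g <- n_mod_genes + n_noise
  genes <- sprintf("G%04d", seq_len(n_g))
  module <- c(rep(seq_len(n_modules), each = module_size),
              rep(NA_integer_, n_noise))
  mat <- matrix(stats::rnorm(n_g * n_samples), n_g, n_samples)
  if (n_modules > 0) {
    factors <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
    idx <- seq_len(n_mod_genes)
    mat[idx, ] <- sqrt(rho) * factors[module[idx], , drop = FALSE] +
      sqrt(1 - rho) * mat[idx, , drop = FALSE]
  }
  dimnames(mat) <- list(genes, sprintf("S%04d", seq_len(n_samples)))
  list(mat = mat, truth = tibble::tibble(gene = genes, module = module))
}

#' Configuration for a synthetic tumour proteome
#'
#' Defaults emulate a large published melanoma proteome matrix: 505 samples
#' in six planted blocks (the largest of 142 samples), ~1200 proteoforms on a
#' log2 normalised-abundance scale, block-wise abundance shifts, and
#' missing-not-at-random (MNAR) values whose probability is a decreasing
#' logistic function of the true abundance — so low-abundance measurements
#' are preferentially missing and the blocks differ in both abundance and
#' missingness, the two signals the tree-cut stratification uses. A GG
#' fraction of 0.4 with planted GG coexpression modules supports the
#' downstream network flow; a small fraction of genes contribute two
#' proteoforms (`SYMBOL.1`, `SYMBOL.2`).
#'
#' @param n_proteins,n_samples Matrix dimensions.
#' @param block_sizes Planted sample-block sizes (must sum to `n_samples`).
#' @param block_shift Per-block abundance shift (log2 units).
#' @param gg_fraction Fraction of proteins flagged GG.
#' @param proteoform_dup_fraction Fraction of genes with a second proteoform.
#' @param module_spec Planted GG coexpression modules (`size`, `rho`).
#' @param rho_between Between-module gene correlation (shared global factor),
#'   connecting the planted modules into one giant component.
#' @param missing_rate Target marginal missingness.
#' @param mnar_steepness Logistic scale of the MNAR mechanism (log2 units).
#' @param block_signature_fraction Fraction of proteins per block carrying a
#'   block-specific high-missingness signature (batch-like pattern).
#' @param noise_sd Residual standard deviation.
#' @return A `proteome_sim_config` list.
#' @export
proteome_sim_config <- function(n_proteins = 12000, n_samples = 505,
                                block_sizes = c(90, 80, 142, 70, 63, 60),
                                block_shift = c(0, 2, 4, -2, 6, -4),
                                gg_fraction = 0.12,
                                proteoform_dup_fraction = 0.05,
                                module_spec = tibble::tibble(
                                  size = rep(35L, 14), rho = rep(0.7, 14)
                                ),
                                rho_between = 0.45,
                                missing_rate = 0.3, mnar_steepness = 1.2,
                                block_signature_fraction = 0.08,
                                noise_sd = 1) {
  stopifnot(sum(block_sizes) == n_samples,
            length(block_shift) == length(block_sizes),
            missing_rate >= 0, missing_rate < 1,
            mnar_steepness > 0, gg_fraction >= 0, gg_fraction <= 1,
            block_signature_fraction >= 0, block_signature_fraction < 1)
  module_spec <- tibble::as_tibble(module_spec)
  if (nrow(module_spec) > 0) {
    stopifnot(rho_between >= 0, all(rho_between < module_spec$rho))
  }
  structure(
    list(n_proteins = n_proteins, n_samples = n_samples,
         block_sizes = block_sizes, block_shift = block_shift,
         gg_fraction = gg_fraction,
         proteoform_dup_fraction = proteoform_dup_fraction,
         module_spec = module_spec, rho_between = rho_between,
         missing_rate = missing_rate, mnar_steepness = mnar_steepness,
         block_signature_fraction = block_signature_fraction,
         noise_sd = noise_sd),
    class = "proteome_sim_config"
  )
}

#' Simulate a tumour proteome matrix with MNAR missingness
#'
#' @param cfg A [proteome_sim_config()].
#' @param seed Integer seed; pure function of `(cfg, seed)`.
#' @return A list of class `sim_proteome` with `mat` (proteoforms x samples,
#'   containing `NA`), `truth` (lists `proteins` and `samples` with planted
#'   block/module labels), and `config`.
#' @export
simulate_proteome <- function(cfg = proteome_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "proteome_sim_config"))
  if (cfg$missing_rate >= 1) stop("missing_rate must be < 1", call. = FALSE)
  set.seed(seed)
  n_p <- cfg$n_proteins
  n_s <- cfg$n_samples
  n_blocks <- length(cfg$block_sizes)
  block <- rep(seq_len(n_blocks), cfg$block_sizes)
  samples <- sprintf("P%04d", seq_len(n_s))

  gene_sym <- sprintf("GENE%04d", seq_len(n_p))
  dup <- stats::runif(n_p) < cfg$proteoform_dup_fraction
  protein_gene <- c(gene_sym, gene_sym[dup])
  protein_id <- c(ifelse(dup, paste0(gene_sym, ".1"), gene_sym),
                  paste0(gene_sym[dup], ".2"))
  n_rows <- length(protein_id)

  is_gg_gene <- stats::runif(n_p) < cfg$gg_fraction
  is_gg <- is_gg_gene[match(protein_gene, gene_sym)]

  module <- rep(NA_integer_, n_rows)
  ms <- cfg$module_spec
  if (nrow(ms) > 0) {
    pool <- sample(which(is_gg))
    for (m in seq_len(nrow(ms))) {
      pool_m <- pool[is.na(module[pool])]
      if (length(pool_m) < ms$size[m]) {
        stop("not enough GG proteins for module ", m, call. = FALSE)
      }
      module[pool_m[seq_len(ms$size[m])]] <- m
    }
  }

  # background proteome broadly expressed; GG proteins mostly low-abundance
  # (gametogenesis genes are largely silent in somatic tissue) except the
  # planted coexpression modules, which are robustly expressed
  baseline <- stats::runif(n_rows, 3, 12)
  baseline[is_gg] <- stats::runif(sum(is_gg), 0, 6)
  baseline[!is.na(module)] <- stats::runif(sum(!is.na(module)), 7, 12)
  mat <- baseline + cfg$noise_sd * matrix(stats::rnorm(n_rows * n_s), n_rows, n_s)
  if (nrow(ms) > 0) {
    factors <- module_factors(ms$rho, cfg$rho_between, n_s)
    for (m in seq_len(nrow(ms))) {
      rows <- which(module == m)
      rho <- ms$rho[m]
      eps <- matrix(stats::rnorm(length(rows) * n_s), length(rows), n_s)
      mat[rows, ] <- baseline[rows] + cfg$noise_sd *
        (sqrt(rho) * matrix(factors[m, ], length(rows), n_s, byrow = TRUE) +
           sqrt(1 - rho) * eps)
    }
  }
  mat <- mat + matrix(cfg$block_shift[block], n_rows, n_s, byrow = TRUE)
  dimnames(mat) <- list(protein_id, samples)

  # MNAR: P(missing | x) = plogis((x0 - x) / tau), plus a block-specific
  # missingness signature (a random protein subset per block that is almost
  # always missing there, the batch-like pattern real cohorts show); x0 is
  # calibrated so the marginal missingness matches cfg$missing_rate
  if (cfg$missing_rate > 0) {
    tau <- cfg$mnar_steepness
    sig <- matrix(FALSE, n_rows, n_s)
    if (cfg$block_signature_fraction > 0) {
      for (b in seq_len(n_blocks)) {
        sig_rows <- sample.int(n_rows,
                               round(cfg$block_signature_fraction * n_rows))
        sig[sig_rows, block == b] <- TRUE
      }
    }
    p_missing <- function(x0) {
      p <- stats::plogis((x0 - mat) / tau)
      p[sig] <- pmax(p[sig], 0.95)
      p
    }
    x0 <- stats::uniroot(
      function(x0) mean(p_missing(x0)) - cfg$missing_rate,
      interval = range(mat) + c(-50, 50)
    )$root
    miss <- matrix(stats::runif(n_rows * n_s), n_rows, n_s) < p_missing(x0)
    mat[miss] <- NA_real_
  }

  structure(
    list(
      mat = mat,
      truth = list(
        proteins = tibble::tibble(protein = protein_id, gene = protein_gene,
                                  is_gg = is_gg, module = module),
        samples = tibble::tibble(sample = samples, block = block)
      ),
      config = cfg
    ),
    class = "sim_proteome"
  )
}
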