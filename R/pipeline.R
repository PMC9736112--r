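#' Configuration of the end-to-end flows
#'
#' Collects the tunable parameters of the transcriptome and proteome flows in
#' one place; every value defaults to the pipeline's standard analysis
#' conditions.
#'
#' @param padj_max,abs_logfc_min DE filter thresholds.
#' @param alpha Significance level for enrichment calls.
#' @param min_gg_profile Eligibility bound for phylostratigraphic profiling
#'   (strictly more GG-up genes than this).
#' @param purity_min,min_wgd_samples,min_up_genes Cohort eligibility rules.
#' @param tpm_min,expr_fraction Transcriptome low-expression filter.
#' @param thresholds,n_sets,set_size,n_shuffles,calibration_alpha Threshold
#'   calibration parameters.
#' @param inflation MCL granularity.
#' @param cut_height,linkage Proteome sample stratification.
#' @param min_units,min_fraction Proteome expression filter.
#' @param select_cluster Proteome sample cluster to analyse; `NULL` selects
#'   the largest.
#' @return A `flow_config` list.
#' @export
flow_config <- function(padj_max = 0.05, abs_logfc_min = 0.5, alpha = 0.05,
                        min_gg_profile = 10,
                        purity_min = 0.5, min_wgd_samples = 50,
                        min_up_genes = 100,
                        tpm_min = 2, expr_fraction = 0.2,
                        thresholds = c(0.6, 0.7, 0.8, 0.9),
                        n_sets = 50, set_size = 300, n_shuffles = 50,
                        calibration_alpha = 0.001,
                        inflation = 2.5,
                        cut_height = 1400, linkage = "complete",
                        min_units = 5, min_fraction = 0.2,
                        select_cluster = NULL) {
  structure(as.list(environment()), class = "flow_config")
}

#' Read a flow configuration from YAML
#'
#' Keys mirror the arguments of [flow_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `flow_config`.
#' @export
read_flow_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(flow_config)))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(flow_config, vals)
}

stage_row <- function(stage, status, n_in = NA_integer_, n_out = NA_integer_,
                      note = NA_character_) {
  tibble::tibble(stage = stage, status = status,
                 n_in = as.integer(n_in), n_out = as.integer(n_out),
                 note = note)
}

#' Run the transcriptome analysis flow
#'
#' Executes the full ploidy-stratified coexpression analysis on one cohort:
#' DE filtering, GG enrichment calls, phylostratigraphic profiling of the
#' upregulated GG genes, cohort eligibility (purity cutoff, WGD+ sample and
#' upregulated-gene minima), low-expression filtering of the WGD+ matrix,
#' surrogate-calibrated threshold selection, network construction over the
#' upregulated genes, giant-component metrics, MCL clustering, and
#' annotation-module enrichment of the giant component against the DE-table
#' universe. Ineligible cohorts stop early with the reason recorded; no
#' stage-only arithmetic exists — every reported number is recomputable from
#' the corresponding exported function.
#'
#' @param de DE table (`gene`, `logFC`, `pAdj`).
#' @param mat Expression matrix (genes x samples, TPM-like scale).
#' @param ploidy Ploidy calls (`sample`, `wgd`, `purity`).
#' @param catalog GG catalogue.
#' @param annotations Optional annotation sets for module enrichment.
#' @param phylo_annot Optional phylostratum annotation (`gene`,
#'   `phylostratum`).
#' @param tumour_type Cohort label.
#' @param config A [flow_config()].
#' @param seed Integer seed (threshold calibration).
#' @param out_dir Optional directory; when given, summary TSVs, the edge
#'   list, and SIF are written there.
#' @return A list of class `wgdnet_run`: `stages` (tibble log), `results`
#'   (named list of intermediate objects), `summary` (cohort-level one-row
#'   tibble), `config`, `seed`.
#' @export
run_transcriptome_flow <- function(de, mat, ploidy, catalog,
                                   annotations = NULL, phylo_annot = NULL,
                                   tumour_type = "COHORT",
                                   config = flow_config(), seed = 1,
                                   out_dir = NULL) {
  stages <- list()
  results <- list()

  sig <- filter_de(de, config$padj_max, config$abs_logfc_min)
  up <- sig$gene[sig$direction == "up"]
  down <- sig$gene[sig$direction == "down"]
  stages[[1]] <- stage_row("filter_de", "ok", nrow(de), nrow(sig))
  results$de_filtered <- sig

  call <- call_enrichment(up, down, unique(de$gene), catalog,
                          alpha = config$alpha, tumour_type = tumour_type)
  stages[[2]] <- stage_row("gg_enrichment", "ok", length(up), call$k_up_gg)
  results$enrichment_call <- call

  gg_up <- filter_by_catalog(tibble::tibble(gene = up), catalog)$gene
  if (!is.null(phylo_annot)) {
    if (eligible_for_profile(gg_up, config$min_gg_profile)) {
      prof <- phylo_profile(gg_up, phylo_annot)
      ref <- phylo_profile(unique(de$gene), phylo_annot)
      results$phylo_profile <- prof
      results$phylo_comparison <- compare_to_reference(prof, ref)
      stages[[3]] <- stage_row("phylo_profile", "ok", length(gg_up),
                               attr(prof, "n_annotated"))
    } else {
      stages[[3]] <- stage_row(
        "phylo_profile", "skipped", length(gg_up), 0,
        paste0("<=", config$min_gg_profile, " upregulated GG genes"))
    }
  }

  strat <- stratify_by_wgd(mat, ploidy, purity_min = config$purity_min,
                           min_wgd_samples = config$min_wgd_samples,
                           min_up_genes = config$min_up_genes, up_genes = up)
  results$eligibility <- strat$eligibility
  stages[[length(stages) + 1]] <- stage_row("stratify_by_wgd", "ok",
                                            ncol(mat),
                                            strat$eligibility$n_wgd_plus)
  run <- function() {
    structure(list(stages = dplyr::bind_rows(stages), results = results,
                   summary = flow_summary(tumour_type, call, results),
                   config = config, seed = seed),
              class = "wgdnet_run")
  }
  if (!strat$eligibility$eligible) {
    stages[[length(stages) + 1]] <- stage_row(
      "eligibility", "stopped", note = sprintf(
        "%d WGD+ samples (min %d), %d upregulated genes (min %d)",
        strat$eligibility$n_wgd_plus, config$min_wgd_samples,
        length(up), config$min_up_genes))
    return(write_flow_outputs(run(), out_dir))
  }

  expressed <- low_expression_filter(strat$wgd_plus, config$tpm_min,
                                     config$expr_fraction)
  stages[[length(stages) + 1]] <- stage_row("low_expression_filter", "ok",
                                            nrow(strat$wgd_plus),
                                            nrow(expressed))

  calib <- calibrate_threshold(expressed, thresholds = config$thresholds,
                               n_sets = config$n_sets,
                               set_size = config$set_size,
                               n_shuffles = config$n_shuffles,
                               alpha = config$calibration_alpha, seed = seed)
  results$calibration <- calib
  stages[[length(stages) + 1]] <- stage_row(
    "calibrate_threshold",
    if (is.na(calib$chosen_threshold)) "stopped" else "ok",
    note = if (is.na(calib$chosen_threshold)) {
      "no threshold separates real from surrogate data"
    } else {
      paste("chosen", calib$chosen_threshold)
    })
  if (is.na(calib$chosen_threshold)) return(write_flow_outputs(run(), out_dir))

  up_expressed <- intersect(up, rownames(expressed))
  corr <- pairwise_pearson(expressed, up_expressed)
  g <- build_graph(corr, calib$chosen_threshold)
  results$graph <- g
  stages[[length(stages) + 1]] <- stage_row("build_graph", "ok",
                                            length(up_expressed),
                                            igraph::ecount(g))

  giant <- giant_component(g)
  results$giant <- giant
  results$metrics <- graph_metrics(g)
  stages[[length(stages) + 1]] <- stage_row("giant_component", "ok",
                                            igraph::vcount(g),
                                            igraph::vcount(giant))

  results$mcl <- mcl(giant, inflation = config$inflation)
  stages[[length(stages) + 1]] <- stage_row("mcl", "ok",
                                            igraph::vcount(giant),
                                            results$mcl$n_clusters)

  if (!is.null(annotations)) {
    results$module_enrichment <- enrich_modules(
      igraph::V(giant)$name, annotations, unique(de$gene),
      alpha = config$alpha)
    stages[[length(stages) + 1]] <- stage_row(
      "module_enrichment", "ok", igraph::vcount(giant),
      sum(results$module_enrichment$significant))
  }

  write_flow_outputs(run(), out_dir)
}

flow_summary <- function(tumour_type, call, results) {
  metrics <- results$metrics
  tibble::tibble(
    tumour_type = tumour_type,
    n_up = call$n_up, k_up_gg = call$k_up_gg,
    enriched_up = call$enriched_up,
    depleted_down = call$depleted_down,
    trend_up = call$trend_up,
    n_wgd_samples = results$eligibility$n_wgd_plus %||% NA_integer_,
    eligible = results$eligibility$eligible %||% NA,
    chosen_threshold = if (!is.null(results$calibration)) {
      results$calibration$chosen_threshold
    } else {
      NA_real_
    },
    pct_giant = if (!is.null(metrics)) 100 * metrics$giant_fraction else NA_real_,
    avg_clustering = if (!is.null(metrics)) metrics$avg_clustering else NA_real_,
    meiotic_enriched = if (!is.null(results$module_enrichment)) {
      any(results$module_enrichment$significant)
    } else {
      NA
    }
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_flow_outputs <- function(run, out_dir) {
  if (is.null(out_dir)) return(run)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$stages, file.path(out_dir, "stages.tsv"))
  readr::write_tsv(run$summary, file.path(out_dir, "summary.tsv"))
  if (!is.null(run$results$calibration)) {
    readr::write_tsv(run$results$calibration$summary,
                     file.path(out_dir, "calibration.tsv"))
  }
  if (!is.null(run$results$graph)) {
    write_edge_list(run$results$graph, file.path(out_dir, "network.tsv"))
    write_sif(run$results$graph, file.path(out_dir, "network.sif"))
  }
  if (!is.null(run$results$module_enrichment)) {
    readr::write_tsv(run$results$module_enrichment,
                     file.path(out_dir, "module_enrichment.tsv"))
  }
  run
}

#' @export
print.wgdnet_run <- function(x, ...) {
  cat("<wgdnet_run> seed ", x$seed, "\n", sep = "")
  print(x$stages)
  invisible(x)
}

#' Run the proteome analysis flow
#'
#' Stratifies the samples by hierarchical clustering with a fixed tree cut,
#' selects one sample cluster (the largest by default), filters lowly
#' expressed proteoforms, imputes missing values at the observed minimum,
#' restricts to GG proteoforms, calibrates the correlation threshold against
#' surrogate data, builds the coexpression network, and analyses its giant
#' component (metrics, MCL, annotation-module enrichment against the
#' whole-proteome universe).
#'
#' @param mat Proteome matrix (proteoforms x samples, log2 normalised
#'   abundances, `NA` for missing).
#' @param catalog GG catalogue.
#' @param annotations Optional annotation sets.
#' @param config A [flow_config()].
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return A `wgdnet_run` (see [run_transcriptome_flow()]).
#' @export
run_proteome_flow <- function(mat, catalog, annotations = NULL,
                              config = flow_config(), seed = 1,
                              out_dir = NULL) {
  stages <- list()
  results <- list()

  clustering <- cluster_samples(mat, cut_height = config$cut_height,
                                linkage = config$linkage)
  results$clustering <- clustering
  stages[[1]] <- stage_row("cluster_samples", "ok", ncol(mat),
                           clustering$n_clusters)

  target <- config$select_cluster
  if (is.null(target)) {
    sizes <- table(clustering$clusters$cluster)
    target <- as.integer(names(sizes)[which.max(sizes)])
  }
  selected <- select_cluster(mat, clustering, target)
  stages[[2]] <- stage_row("select_cluster", "ok", ncol(mat), ncol(selected),
                           paste("cluster", target))

  expressed <- expression_filter(selected, config$min_units,
                                 config$min_fraction)
  stages[[3]] <- stage_row("expression_filter", "ok", nrow(selected),
                           nrow(expressed))

  complete <- min_impute(expressed)
  stages[[4]] <- stage_row("min_impute", "ok", sum(is.na(expressed)), 0)

  gg_rows <- filter_by_catalog(tibble::tibble(gene = rownames(complete)),
                               catalog)$gene
  gg_mat <- complete[gg_rows, , drop = FALSE]
  results$n_gg_proteoforms <- nrow(gg_mat)
  stages[[5]] <- stage_row("filter_gg", "ok", nrow(complete), nrow(gg_mat))

  run <- function() {
    structure(list(stages = dplyr::bind_rows(stages), results = results,
                   summary = proteome_summary(results),
                   config = config, seed = seed),
              class = "wgdnet_run")
  }

  calib <- calibrate_threshold(gg_mat, thresholds = config$thresholds,
                               n_sets = config$n_sets,
                               set_size = config$set_size,
                               n_shuffles = config$n_shuffles,
                               alpha = config$calibration_alpha, seed = seed)
  results$calibration <- calib
  stages[[6]] <- stage_row(
    "calibrate_threshold",
    if (is.na(calib$chosen_threshold)) "stopped" else "ok",
    note = if (is.na(calib$chosen_threshold)) {
      "no threshold separates real from surrogate data"
    } else {
      paste("chosen", calib$chosen_threshold)
    })
  if (is.na(calib$chosen_threshold)) return(write_flow_outputs(run(), out_dir))

  corr <- pairwise_pearson(gg_mat)
  g <- build_graph(corr, calib$chosen_threshold)
  results$graph <- g
  stages[[7]] <- stage_row("build_graph", "ok", nrow(gg_mat),
                           igraph::ecount(g))

  giant <- giant_component(g)
  results$giant <- giant
  results$metrics <- graph_metrics(g)
  stages[[8]] <- stage_row("giant_component", "ok", igraph::vcount(g),
                           igraph::vcount(giant))

  results$mcl <- mcl(giant, inflation = config$inflation)
  stages[[9]] <- stage_row("mcl", "ok", igraph::vcount(giant),
                           results$mcl$n_clusters)

  if (!is.null(annotations)) {
    universe <- proteoform_to_symbol(rownames(mat))
    results$module_enrichment <- enrich_modules(
      proteoform_to_symbol(igraph::V(giant)$name), annotations, universe,
      alpha = config$alpha)
    results$mcl1_enrichment <- enrich_modules(
      proteoform_to_symbol(mcl_cluster_nodes(results$mcl, 1)), annotations,
      universe, alpha = config$alpha)
    stages[[10]] <- stage_row(
      "module_enrichment", "ok", igraph::vcount(giant),
      sum(results$module_enrichment$significant))
  }

  write_flow_outputs(run(), out_dir)
}

proteome_summary <- function(results) {
  metrics <- results$metrics
  tibble::tibble(
    n_sample_clusters = results$clustering$n_clusters,
    n_gg_proteoforms = results$n_gg_proteoforms %||% NA_integer_,
    chosen_threshold = if (!is.null(results$calibration)) {
      results$calibration$chosen_threshold
    } else {
      NA_real_
    },
    n_giant = if (!is.null(results$giant)) {
      igraph::vcount(results$giant)
    } else {
      NA_integer_
    },
    n_edges = if (!is.null(results$graph)) {
      igraph::ecount(results$graph)
    } else {
      NA_integer_
    },
    avg_clustering = if (!is.null(metrics)) metrics$avg_clustering else NA_real_,
    avg_shortest_path = if (!is.null(metrics)) {
      metrics$avg_shortest_path
    } else {
      NA_real_
    },
    meiotic_enriched = if (!is.null(results$module_enrichment)) {
      any(results$module_enrichment$significant)
    } else {
      NA
    }
  )
}
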