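#' Read a phylostratum annotation TSV
#'
#' Expects columns `gene` and `phylostratum` (integers 1-16, stratum 1 being
#' the oldest, cellular organisms, and 16 Homo sapiens).
#'
#' @param path TSV file path.
#' @return Tibble with normalised symbols, one stratum per gene.
#' @export
read_phylostrata <- function(path) {
  annot <- readr::read_tsv(path, show_col_types = FALSE)
  validate_phylo_annotation(annot)
}

validate_phylo_annotation <- function(annot, n_strata = 16) {
  need <- c("gene", "phylostratum")
  missing <- setdiff(need, names(annot))
  if (length(missing) > 0) {
    stop("phylostratum annotation lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  annot <- tibble::as_tibble(annot)
  annot$gene <- normalise_symbols(annot$gene)
  annot$phylostratum <- as.integer(annot$phylostratum)
  if (any(annot$phylostratum < 1 | annot$phylostratum > n_strata, na.rm = TRUE)) {
    stop("phylostrata outside [1, ", n_strata, "]", call. = FALSE)
  }
  if (anyDuplicated(annot$gene)) {
    stop("multiple strata for gene(s): ",
         paste(utils::head(unique(annot$gene[duplicated(annot$gene)]), 5),
               collapse = ", "), call. = FALSE)
  }
  annot
}

#' Phylostratigraphic profile of a gene set
#'
#' Counts the members of a gene set per phylostratum. Genes absent from the
#' annotation are tallied separately (`n_unannotated`) and excluded from the
#' proportions, never silently dropped.
#'
#' @param genes Character vector of gene symbols.
#' @param annot Annotation data frame (`gene`, `phylostratum`).
#' @param n_strata Number of strata (default 16).
#' @return Tibble of class `phylo_profile` with columns `stratum`, `count`,
#'   `proportion`, plus attributes `n_annotated`, `n_unannotated`, and
#'   `unannotated` (the symbols themselves).
#' @export
phylo_profile <- function(genes, annot, n_strata = 16) {
  annot <- validate_phylo_annotation(annot, n_strata)
  if (nrow(annot) == 0) stop("empty annotation", call. = FALSE)
  genes <- unique(normalise_symbols(genes))
  strata <- annot$phylostratum[match(genes, annot$gene)]
  unannotated <- genes[is.na(strata)]
  strata <- strata[!is.na(strata)]
  counts <- tabulate(strata, nbins = n_strata)
  n_annot <- sum(counts)
  out <- tibble::tibble(
    stratum = seq_len(n_strata),
    count = counts,
    proportion = if (n_annot > 0) counts / n_annot else rep(0, n_strata)
  )
  attr(out, "n_annotated") <- n_annot
  attr(out, "n_unannotated") <- length(unannotated)
  attr(out, "unannotated") <- unannotated
  class(out) <- c("phylo_profile", class(out))
  out
}

#' Compare a phylostratigraphic profile to a reference
#'
#' Per-stratum enrichment of a gene set against a reference background:
#' the proportion ratio and a right-sided hypergeometric p-value, drawing the
#' set's annotated genes from the reference population.
#'
#' @param profile A [phylo_profile()] of the gene set.
#' @param reference A [phylo_profile()] of the reference (must be at least as
#'   large as the set).
#' @return Tibble with `stratum`, set and reference counts/proportions,
#'   `ratio` (`NA` with `undefined = TRUE` where the reference proportion is
#'   zero), and `p_value`.
#' @export
compare_to_reference <- function(profile, reference) {
  n_set <- attr(profile, "n_annotated")
  n_ref <- attr(reference, "n_annotated")
  if (is.null(n_set) || is.null(n_ref)) {
    stop("inputs must be phylo_profile objects", call. = FALSE)
  }
  if (n_ref == 0) stop("reference profile has no annotated genes", call. = FALSE)
  if (n_ref < n_set) {
    stop("reference must be at least as large as the profiled set", call. = FALSE)
  }
  tibble::tibble(
    stratum = profile$stratum,
    count_set = profile$count,
    count_ref = reference$count,
    proportion_set = profile$proportion,
    proportion_ref = reference$proportion,
    undefined = .data$proportion_ref == 0 & .data$proportion_set > 0,
    ratio = ifelse(.data$proportion_ref > 0,
                   .data$proportion_set / .data$proportion_ref, NA_real_),
    p_value = purrr::map2_dbl(
      .data$count_set, .data$count_ref,
      ~ hypergeom_tail(.x, .y, n_set, n_ref)
    )
  )
}

#' Locate peaks of a phylostratigraphic profile
#'
#' A peak is a stratum whose proportion is strictly greater than both
#' neighbours (end strata compare to their single neighbour).
#'
#' @param profile A [phylo_profile()].
#' @return Integer vector of peak strata.
#' @export
profile_peaks <- function(profile) {
  p <- profile$proportion
  n <- length(p)
  if (n < 2) return(profile$stratum[p > 0])
  left <- c(-Inf, p[-n])
  right <- c(p[-1], -Inf)
  profile$stratum[p > left & p > right]
}

#' Eligibility of a cohort for a GG phylostratigraphic profile
#'
#' A cohort qualifies when it has strictly more than `min_gg` ploidy-
#' upregulated GG genes.
#'
#' @param gg_up Character vector of upregulated GG genes.
#' @param min_gg Threshold (default 10; `> 10` is required, so 10 fails).
#' @return Logical scalar.
#' @export
eligible_for_profile <- function(gg_up, min_gg = 10) {
  length(unique(gg_up)) > min_gg
}
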