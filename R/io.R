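#' Read a one-symbol-per-line gene list
#'
#' Blank lines and `#` comment lines are ignored; symbols are normalised.
#'
#' @param path File path.
#' @return Character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(normalise_symbols(lines))
}

#' Read gene sets in GMT format
#'
#' GMT is tab-delimited: set name, description, then member symbols.
#'
#' @param path File path.
#' @return Tibble with columns `term_id`, `term_name`, `genes` (list-column of
#'   character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) {
    stop("GMT lines without members: ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    term_id = vapply(fields, `[[`, "", 1),
    term_name = vapply(fields, `[[`, "", 2),
    genes = lapply(fields, function(f) unique(normalise_symbols(f[-(1:2)])))
  )
}

#' Write gene sets in GMT format
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(
    sets[c("term_id", "term_name", "genes")],
    function(term_id, term_name, genes) {
      paste(c(term_id, term_name, genes), collapse = "\t")
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects a header with columns `gene`, `logFC`, `pAdj` (extra columns kept).
#'
#' @param path TSV file path.
#' @return Tibble with normalised gene symbols.
#' @export
read_de_table <- function(path) {
  de <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene", "logFC", "pAdj")
  missing <- setdiff(need, names(de))
  if (length(missing) > 0) {
    stop("DE table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  de$gene <- normalise_symbols(de$gene)
  de
}

#' Read per-sample ploidy calls
#'
#' Expects columns `sample`, `wgd` (0/1 or logical), `purity`, and optionally
#' `ploidy`, in the style of ABSOLUTE output summaries.
#'
#' @param path TSV file path.
#' @return Tibble with `wgd` as logical.
#' @export
read_ploidy_calls <- function(path) {
  calls <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample", "wgd", "purity")
  missing <- setdiff(need, names(calls))
  if (length(missing) > 0) {
    stop("ploidy table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  calls$wgd <- as.logical(calls$wgd)
  if (any(calls$purity < 0 | calls$purity > 1, na.rm = TRUE)) {
    stop("purity values outside [0, 1]", call. = FALSE)
  }
  calls
}

#' Read an expression matrix TSV
#'
#' First column holds gene/proteoform identifiers; remaining columns are
#' samples. Empty cells and `NA` become missing values.
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes x samples, with identifier rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1]])
  mat
}

#' Write an expression matrix TSV
#'
#' @param mat Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, id_col = "gene") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the edges of a coexpression graph as a tibble
#'
#' @param g An igraph graph with an `r` edge attribute.
#' @return Tibble with columns `source`, `target`, `r`.
#' @export
graph_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  tibble::tibble(
    source = el[, 1],
    target = el[, 2],
    r = if ("r" %in% igraph::edge_attr_names(g)) {
      igraph::E(g)$r
    } else {
      rep(NA_real_, nrow(el))
    }
  )
}

#' Write a graph as an edge-list TSV
#'
#' Columns `source`, `target`, `r` (signed correlation kept as an attribute of
#' the unsigned edge).
#'
#' @param g An igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  readr::write_tsv(graph_edges(g), path)
  invisible(path)
}

#' Read an edge-list TSV written by [write_edge_list()]
#'
#' Isolated nodes are not representable in an edge list and are lost.
#'
#' @param path File path.
#' @return An igraph graph with an `r` edge attribute.
#' @export
read_edge_list <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  g <- igraph::graph_from_data_frame(edges[c("source", "target")],
                                     directed = FALSE)
  if ("r" %in% names(edges)) igraph::E(g)$r <- edges$r
  g
}

#' Write a graph in SIF (simple interaction format)
#'
#' Edges use the interaction type `coexp`; isolated nodes are written as bare
#' single-column lines, which Cytoscape accepts.
#'
#' @param g An igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(g, path) {
  el <- igraph::as_edgelist(g)
  lines <- if (nrow(el) > 0) paste(el[, 1], "coexp", el[, 2], sep = "\t") else character()
  isolated <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, isolated), path)
  invisible(path)
}
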