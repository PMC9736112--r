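#' Normalise gene symbols
#'
#' Uppercases, trims surrounding whitespace, and collapses whitespace found
#' *inside* a symbol (printed lists sometimes break a symbol across a space,
#' e.g. `"SYC E1L"` for SYCE1L). No alias resolution is attempted: the
#' normalisation is deterministic and fully offline.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of normalised symbols.
#' @export
#' @examples
#' normalise_symbols(c(" sycp1 ", "SYC E1L"))
normalise_symbols <- function(x) {
  x <- toupper(trimws(x))
  gsub("[[:space:]]+", "", x)
}

#' Parse a printed curated-addendum gene list
#'
#' Parses free text in which gene symbols are separated by commas (or, when no
#' comma is present, by whitespace). Symbols are normalised with
#' [normalise_symbols()] and deduplicated preserving first occurrence.
#'
#' @param text A character scalar (or vector, concatenated) holding the list.
#' @return Character vector of unique, uppercase symbols, in order of first
#'   appearance. Empty input yields an empty vector with a warning.
#' @export
#' @examples
#' parse_curated_addendum("SYCP1, sycp1, SYC E1L, TEX11")
parse_curated_addendum <- function(text) {
  text <- paste(text, collapse = "\n")
  if (!nzchar(trimws(text))) {
    warning("empty addendum text; returning no symbols", call. = FALSE)
    return(character())
  }
  tokens <- if (grepl(",", text, fixed = TRUE)) {
    strsplit(text, ",", fixed = TRUE)[[1]]
  } else {
    strsplit(text, "[[:space:]]+")[[1]]
  }
  tokens <- normalise_symbols(tokens)
  unique(tokens[nzchar(tokens)])
}

#' The bundled curated addendum of meiosis/gametogenesis genes
#'
#' Returns the manually curated list of additional gametogenesis genes shipped
#' with the package (22 symbols, synaptonemal-complex and meiosis regulators
#' such as SYCP1-3, HORMAD2, MEIOB, TEX11), parsed from its raw printed form.
#'
#' @return Character vector of 22 symbols.
#' @export
curated_addendum <- function() {
  path <- system.file("extdata", "curated_addendum.txt", package = "wgdnet")
  parse_curated_addendum(readLines(path, warn = FALSE))
}

#' Assemble a gametogenesis-related (GG) gene catalogue
#'
#' Takes named source gene lists (e.g. cancer-testis antigens, germ-cell
#' -specific genes, meiosis-database genes) plus a curated addendum, and
#' returns the deduplicated union with per-gene source provenance. A gene
#' appearing in several sources carries all of their flags; sources are never
#' allowed to drop one another's members.
#'
#' @param source_lists Named list of character vectors of gene symbols.
#' @param addendum Character vector of extra curated symbols (flagged
#'   `"curated"`).
#' @return A tibble of class `gg_catalog` with columns `symbol`, `sources`
#'   (list-column of character flags), `n_sources`, and `phylostratum`
#'   (integer, `NA` until annotated with [annotate_phylostrata()]). The input
#'   list names are recorded in the `"provenance"` attribute.
#' @export
#' @examples
#' assemble_gg_set(list(ct = c("MAGEA1", "PRAME"), meiosis = c("DMC1", "PRAME")))
assemble_gg_set <- function(source_lists = list(), addendum = character()) {
  stopifnot(is.list(source_lists))
  if (length(source_lists) > 0 && is.null(names(source_lists))) {
    stop("`source_lists` must be named", call. = FALSE)
  }
  lists <- purrr::map(source_lists, ~ unique(normalise_symbols(.x)))
  lists <- purrr::map(lists, ~ .x[nzchar(.x)])
  addendum <- unique(normalise_symbols(addendum))
  addendum <- addendum[nzchar(addendum)]
  if (length(addendum) > 0) lists <- c(lists, list(curated = addendum))
  if (length(lists) == 0 || sum(lengths(lists)) == 0) {
    stop("all gene sources are empty", call. = FALSE)
  }
  long <- purrr::imap(lists, ~ tibble::tibble(symbol = .x, source = .y))
  long <- dplyr::bind_rows(long)
  catalog <- long |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(sources = list(sort(unique(.data$source))), .groups = "drop") |>
    dplyr::mutate(
      n_sources = lengths(.data$sources),
      phylostratum = NA_integer_
    ) |>
    dplyr::arrange(.data$symbol)
  attr(catalog, "provenance") <- names(lists)
  class(catalog) <- c("gg_catalog", class(catalog))
  catalog
}

#' Annotate a catalogue with phylostrata
#'
#' @param catalog A `gg_catalog` tibble.
#' @param annot A data frame with columns `gene` and `phylostratum` (integers
#'   1-16).
#' @return The catalogue with `phylostratum` filled where known.
#' @export
annotate_phylostrata <- function(catalog, annot) {
  annot <- validate_phylo_annotation(annot)
  idx <- match(catalog$symbol, annot$gene)
  catalog$phylostratum <- annot$phylostratum[idx]
  catalog
}

#' Map proteoform identifiers to gene symbols
#'
#' Proteome matrices may carry several proteoforms of one gene as
#' `SYMBOL<sep>suffix` rows (e.g. `TPM3.2`, `HBA_1`). The mapping strips the
#' first separator and everything after it; identifiers without a separator
#' are returned unchanged (after symbol normalisation). Hyphens are *not*
#' treated as separators, since many HGNC symbols contain them (NKX2-1).
#'
#' @param ids Character vector of gene or proteoform identifiers.
#' @param sep Regular expression matching the proteoform separator.
#' @return Character vector of gene symbols, same length as `ids`.
#' @export
#' @examples
#' proteoform_to_symbol(c("TPM3.2", "DMC1", "HBA_1"))
proteoform_to_symbol <- function(ids, sep = "[._]") {
  normalise_symbols(sub(paste0(sep, ".*$"), "", ids))
}

#' Filter a gene-keyed table by a catalogue
#'
#' Keeps the rows of `table` whose (proteoform-mapped) gene symbol belongs to
#' the catalogue. Row identity is preserved: distinct proteoforms of one gene
#' remain distinct rows.
#'
#' @param table A data frame with a gene-identifier column.
#' @param catalog A `gg_catalog` (or any data frame with a `symbol` column, or
#'   a character vector of symbols).
#' @param gene_col Name of the identifier column in `table`.
#' @param proteoform_sep Separator regex passed to [proteoform_to_symbol()];
#'   set to `NULL` to disable proteoform mapping.
#' @return The subset of `table` (same columns) as a tibble.
#' @export
filter_by_catalog <- function(table, catalog, gene_col = "gene",
                              proteoform_sep = "[._]") {
  if (!gene_col %in% names(table)) {
    stop("column `", gene_col, "` not found in table", call. = FALSE)
  }
  symbols <- catalog_symbols(catalog)
  ids <- table[[gene_col]]
  mapped <- if (is.null(proteoform_sep)) {
    normalise_symbols(ids)
  } else {
    proteoform_to_symbol(ids, sep = proteoform_sep)
  }
  tibble::as_tibble(table)[mapped %in% symbols, , drop = FALSE]
}

catalog_symbols <- function(catalog) {
  if (is.character(catalog)) return(normalise_symbols(catalog))
  if (is.data.frame(catalog) && "symbol" %in% names(catalog)) {
    return(catalog$symbol)
  }
  stop("`catalog` must be a gg_catalog, a data frame with a `symbol` column, ",
       "or a character vector", call. = FALSE)
}

#' @export
print.gg_catalog <- function(x, ...) {
  cat("<gg_catalog> ", nrow(x), " genes from sources: ",
      paste(attr(x, "provenance"), collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Write a catalogue to TSV
#'
#' Sources are joined with `;` in the flat file.
#'
#' @param catalog A `gg_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  flat <- dplyr::mutate(
    tibble::as_tibble(catalog),
    sources = purrr::map_chr(.data$sources, paste, collapse = ";")
  )
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Read a catalogue TSV written by [write_catalog()]
#'
#' @param path File path.
#' @return A `gg_catalog` tibble.
#' @export
read_catalog <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            symbol = "c", sources = "c",
                            phylostratum = "i"))
  catalog <- dplyr::mutate(flat, sources = strsplit(.data$sources, ";", fixed = TRUE))
  attr(catalog, "provenance") <- sort(unique(unlist(catalog$sources)))
  class(catalog) <- c("gg_catalog", class(catalog))
  catalog
}
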