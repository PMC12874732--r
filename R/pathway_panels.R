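#' Construct a pathway panel
#'
#' A panel describes one KEGG pathway of interest: the set of EC numbers on
#' the map, a gene-symbol to EC mapping (one symbol may cover several ECs,
#' e.g. the two glutamate-synthase ECs of `gltBD`), and a grouping of gene
#' symbols into the metabolic processes used for plotting and flow tables.
#'
#' @param pathway_id panel identifier, e.g. `"map00910"`.
#' @param gene_map data.frame with columns `gene`, `ec` (one row per
#'   gene-EC pair) and `process` (one process label per gene symbol).
#' @param ec_list optional character vector of all panel ECs; defaults to
#'   the ECs of `gene_map`. Every gene-mapped EC must be in this set.
#' @return object of class `pathway_panel`: list with `pathway_id`,
#'   `ec_list`, `gene_map` (gene, ec), `process_map` (named character,
#'   gene -> process).
#' @export
pathway_panel <- function(pathway_id, gene_map, ec_list = NULL) {
  stopifnot(all(c("gene", "ec", "process") %in% names(gene_map)))
  gene_map$gene <- as.character(gene_map$gene)
  gene_map$ec <- as.character(gene_map$ec)
  gene_map$process <- as.character(gene_map$process)
  if (is.null(ec_list)) ec_list <- unique(gene_map$ec)
  ec_list <- unique(as.character(ec_list))
  outside <- setdiff(gene_map$ec, ec_list)
  if (length(outside) > 0) {
    stop("gene_map references EC(s) outside ec_list: ",
         paste(outside, collapse = ", "))
  }
  if (anyDuplicated(paste(gene_map$gene, gene_map$ec))) {
    stop("duplicate (gene, ec) pair in gene_map")
  }
  proc_per_gene <- tapply(gene_map$process, gene_map$gene,
                          function(p) length(unique(p)))
  multi <- names(proc_per_gene)[proc_per_gene > 1]
  if (length(multi) > 0) {
    stop("gene(s) with more than one process label: ",
         paste(multi, collapse = ", "))
  }
  first <- !duplicated(gene_map$gene)
  process_map <- setNames(gene_map$process[first], gene_map$gene[first])
  structure(list(pathway_id = pathway_id, ec_list = ec_list,
                 gene_map = gene_map[c("gene", "ec")],
                 process_map = process_map),
            class = "pathway_panel")
}

#' @export
print.pathway_panel <- function(x, ...) {
  cat("pathway_panel ", x$pathway_id, ": ", length(x$ec_list), " ECs, ",
      length(x$process_map), " gene symbols, ",
      length(unique(x$process_map)), " processes\n", sep = "")
  invisible(x)
}

#' Load a packaged or user-supplied pathway panel
#'
#' Two panels ship with the package, frozen from a KEGG snapshot
#' (2025-06): `map00910` (nitrogen metabolism, 39 ECs) and `map00440`
#' (phosphonate and phosphinate metabolism, 31 ECs). Panels are static
#' fixtures, never fetched live, so results are reproducible offline.
#' Note on `phnGHIL`: it is mapped to EC 2.7.8.37 (the syntactically valid
#' form); the variant `12.7.8.37` occasionally seen in print is treated as
#' a typographical error and is not accepted.
#'
#' @param pathway_id `"map00910"`, `"map00440"`, or the path of a panel TSV
#'   with columns `gene`, `ec`, `process`.
#' @return a [pathway_panel()].
#' @export
load_pathway_panel <- function(pathway_id) {
  builtin <- c("map00910", "map00440")
  if (pathway_id %in% builtin) {
    path <- system.file("extdata", paste0("panel_", pathway_id, ".tsv"),
                        package = "taxafun", mustWork = TRUE)
    id <- pathway_id
  } else if (file.exists(pathway_id)) {
    path <- pathway_id
    id <- sub("\\.[^.]*$", "", basename(pathway_id))
  } else {
    stop("unknown pathway_id '", pathway_id, "'; available panels: ",
         paste(builtin, collapse = ", "),
         " (or supply the path of a panel TSV)")
  }
  gm <- read.delim(path, stringsAsFactors = FALSE)
  pathway_panel(id, gm)
}

#' Genes of a panel mapped to a given EC
#'
#' @param panel a [pathway_panel()].
#' @param ec character vector of EC numbers.
#' @return character vector of gene symbols for each EC (`NA` when the EC
#'   carries no symbol in the panel).
#' @export
panel_gene_for_ec <- function(panel, ec) {
  stopifnot(inherits(panel, "pathway_panel"))
  panel$gene_map$gene[match(ec, panel$gene_map$ec)]
}
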