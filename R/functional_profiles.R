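# RPKM arithmetic and the table transformations between stratified
# function x taxon x sample tables and the quantities that get plotted:
# replicate aggregation, pathway subsetting, detection counts, gene
# contribution percentages and noise filtering.

#' Reads Per Kilobase per Million mapped reads
#'
#' `RPKM = count / ((gene_length_bp / 1000) * (total_mapped_reads / 1e6))`.
#'
#' @param read_count non-negative read count (vectorised).
#' @param gene_length_bp gene length in bp (> 0).
#' @param total_mapped_reads library size in mapped reads (> 0).
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(read_count, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be > 0")
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")
  if (any(read_count < 0)) stop("read_count must be >= 0")
  read_count / ((gene_length_bp / 1000) * (total_mapped_reads / 1e6))
}

.table_values <- function(table) {
  if (inherits(table, "stratified_table")) table$values else as.matrix(table)
}

.table_metadata <- function(table, metadata = NULL) {
  if (!is.null(metadata)) return(metadata)
  if (inherits(table, "stratified_table")) return(table$metadata)
  md <- attr(table, "metadata")
  if (is.null(md)) stop("metadata required (none attached to table)")
  md
}

#' Sum replicate columns into one column per treatment
#'
#' Applies to stratified or unstratified tables; the reference design
#' yields exactly seven treatment columns. The grand total is preserved.
#'
#' @param table a [stratified_table()] or a numeric matrix with sample
#'   columns.
#' @param metadata a [sample_metadata()] table (optional when attached to
#'   `table`).
#' @return same shape of object with one column per treatment (treatments
#'   in order of first appearance in the metadata).
#' @export
sum_replicates <- function(table, metadata = NULL) {
  md <- .table_metadata(table, metadata)
  vals <- .table_values(table)
  trts <- unique(md$treatment)
  agg <- vapply(trts, function(t) {
    cols <- md$sample_id[md$treatment == t]
    rowSums(vals[, cols, drop = FALSE])
  }, numeric(nrow(vals)))
  if (nrow(vals) == 1L) agg <- matrix(agg, nrow = 1L,
                                      dimnames = list(NULL, trts))
  colnames(agg) <- trts
  if (inherits(table, "stratified_table")) {
    out <- table
    out$values <- agg
    out$metadata <- sample_metadata(trts, trts, rep(1L, length(trts)))
    out
  } else {
    rn <- rownames(vals)
    rownames(agg) <- rn
    attr(agg, "metadata") <- sample_metadata(trts, trts,
                                             rep(1L, length(trts)))
    agg
  }
}

#' Restrict a table to the ECs of a pathway panel
#'
#' @param table a [stratified_table()] or a matrix with EC row names.
#' @param panel a [pathway_panel()].
#' @return the table restricted to rows whose EC is in `panel$ec_list`.
#' @export
subset_pathway <- function(table, panel) {
  stopifnot(inherits(panel, "pathway_panel"))
  if (inherits(table, "stratified_table")) {
    keep <- table$function_id %in% panel$ec_list
    stratified_table(table$function_id[keep], table$lineage[keep],
                     table$values[keep, , drop = FALSE], table$metadata)
  } else {
    m <- as.matrix(table)
    out <- m[rownames(m) %in% panel$ec_list, , drop = FALSE]
    attr(out, "metadata") <- attr(table, "metadata")
    out
  }
}

#' Count detected panel functions
#'
#' A panel EC is detected iff its summed RPKM is strictly positive in at
#' least one sample (an RPKM of exactly 0 means absent).
#'
#' @param table a [stratified_table()] or matrix with EC row names.
#' @param panel a [pathway_panel()].
#' @return named integer vector `c(n_detected, n_panel)`.
#' @export
detected_function_count <- function(table, panel) {
  stopifnot(inherits(panel, "pathway_panel"))
  if (inherits(table, "stratified_table")) {
    ids <- table$function_id
    vals <- table$values
  } else {
    ids <- rownames(table)
    vals <- as.matrix(table)
  }
  keep <- ids %in% panel$ec_list
  present <- unique(ids[keep][rowSums(vals[keep, , drop = FALSE] > 0) > 0])
  c(n_detected = length(present), n_panel = length(panel$ec_list))
}

#' Per-gene contribution percentages
#'
#' Shares of the total pathway RPKM by gene symbol (summing each symbol's
#' EC rows over all taxa and samples), as reported in per-function
#' contribution statements ("gene X accounted for NN% of total RPKM").
#' ECs carrying no symbol in the panel are grouped under their EC number.
#'
#' @param table a [stratified_table()] or matrix with EC row names;
#'   subset to the panel internally.
#' @param panel a [pathway_panel()].
#' @return data.frame with columns `gene`, `rpkm`, `percent`, sorted by
#'   decreasing share; percentages sum to 100.
#' @export
contribution_percentages <- function(table, panel) {
  stopifnot(inherits(panel, "pathway_panel"))
  if (inherits(table, "stratified_table")) {
    ids <- table$function_id
    vals <- table$values
  } else {
    ids <- rownames(table)
    vals <- as.matrix(table)
  }
  keep <- ids %in% panel$ec_list
  ids <- ids[keep]
  tot_by_ec <- rowSums(vals[keep, , drop = FALSE])
  gene <- panel_gene_for_ec(panel, ids)
  gene[is.na(gene)] <- ids[is.na(gene)]
  rpkm <- tapply(tot_by_ec, gene, sum)
  total <- sum(rpkm)
  if (total <= 0) stop("zero total RPKM: contributions undefined")
  out <- data.frame(gene = names(rpkm), rpkm = as.numeric(rpkm),
                    percent = 100 * as.numeric(rpkm) / total,
                    stringsAsFactors = FALSE)
  out[order(-out$percent, out$gene), , drop = FALSE]
}

#' Per-treatment mean +/- standard error of pathway-total RPKM
#'
#' For each treatment, the per-sample pathway-total RPKM (column sum after
#' panel subsetting) is averaged over replicates; the uncertainty reported
#' is the standard error of that mean (`sd / sqrt(n)`). With a single
#' replicate the mean is reported and the s.e. is `NA`.
#'
#' @param table a [stratified_table()] (replicate-level, not aggregated).
#' @param panel a [pathway_panel()]; subsetting applied internally.
#' @param metadata optional [sample_metadata()] override.
#' @return data.frame with columns `treatment`, `mean`, `se`, `n`.
#' @export
mean_total_rpkm <- function(table, panel, metadata = NULL) {
  md <- .table_metadata(table, metadata)
  sub <- subset_pathway(table, panel)
  totals <- colSums(.table_values(sub))
  trts <- unique(md$treatment)
  out <- lapply(trts, function(t) {
    x <- totals[md$sample_id[md$treatment == t]]
    data.frame(treatment = t, mean = mean(x),
               se = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Filter out low-RPKM noise
#'
#' Removes entries strictly below the threshold; 0 is the identity
#' (filtering off, the default everywhere since reported numbers are
#' unfiltered values). For a stratified table, rows whose values all fall
#' below the threshold are dropped and surviving rows keep only their
#' above-threshold cells (others set to 0); for a flow table, edges below
#' the threshold are dropped.
#'
#' @param x a [stratified_table()], numeric matrix, or `flow_table`.
#' @param threshold RPKM threshold (>= 0).
#' @return filtered object of the same class.
#' @export
noise_filter <- function(x, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (threshold == 0) return(x)
  if (inherits(x, "flow_table")) {
    x$edges <- x$edges[x$edges$weight >= threshold, , drop = FALSE]
    return(x)
  }
  if (inherits(x, "stratified_table")) {
    v <- x$values
    v[v < threshold] <- 0
    keep <- rowSums(v) > 0
    return(stratified_table(x$function_id[keep], x$lineage[keep],
                            v[keep, , drop = FALSE], x$metadata))
  }
  m <- as.matrix(x)
  md <- attr(x, "metadata")
  m[m < threshold] <- 0
  m <- m[rowSums(m) > 0, , drop = FALSE]
  attr(m, "metadata") <- md
  m
}
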