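#' Thresholded Pearson correlation screen
#'
#' Pearson correlation between every (function, soil property) pair,
#' with two-sided t-test p-values and a significance flag at the given
#' alpha. Observations are pairwise complete; pairs with fewer than 3
#' complete observations or a zero-variance side are reported with `NA`
#' and flagged `undefined`. No multiple-testing correction is applied
#' across the grid (matching the reference analysis, which screens at raw
#' p < 0.05).
#'
#' @param properties a [soil_properties()] table.
#' @param gene_table numeric matrix, rows = functions/genes (row names
#'   required), columns = samples matching `properties$sample_id`.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with columns `gene`, `property`, `r`, `p`,
#'   `significant`, `n`, `status` (`ok` / `undefined`).
#' @export
correlation_screen <- function(properties, gene_table, alpha = 0.05) {
  stopifnot(inherits(properties, "soil_properties"))
  gene_table <- as.matrix(gene_table)
  if (is.null(rownames(gene_table))) stop("gene_table needs row names")
  shared <- intersect(properties$sample_id, colnames(gene_table))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  props <- setdiff(names(properties), "sample_id")
  pmat <- as.matrix(properties[match(shared, properties$sample_id), props,
                               drop = FALSE])
  gmat <- gene_table[, shared, drop = FALSE]
  rows <- vector("list", nrow(gmat) * length(props))
  k <- 0L
  for (gi in seq_len(nrow(gmat))) {
    for (pi in seq_along(props)) {
      x <- gmat[gi, ]
      y <- pmat[, pi]
      ok <- !is.na(x) & !is.na(y)
      n_ok <- sum(ok)
      k <- k + 1L
      if (n_ok < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        rows[[k]] <- data.frame(gene = rownames(gmat)[gi],
                                property = props[pi], r = NA_real_,
                                p = NA_real_, significant = NA, n = n_ok,
                                status = "undefined",
                                stringsAsFactors = FALSE)
        next
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      rows[[k]] <- data.frame(gene = rownames(gmat)[gi],
                              property = props[pi],
                              r = unname(ct$estimate), p = ct$p.value,
                              significant = ct$p.value < alpha, n = n_ok,
                              status = "ok", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
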