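#' Taxonomically stratified functional abundance table
#'
#' The central object of the pipeline: an RPKM matrix whose rows are
#' (EC function, taxon lineage) pairs and whose columns are samples.
#' RPKM = reads per kilobase of gene per million mapped reads, a length- and
#' depth-normalised abundance.
#'
#' @param function_id character vector of EC-number strings, one per row.
#' @param lineage character vector of canonical lineage strings (see
#'   [make_lineage()]), one per row.
#' @param values numeric matrix, rows matching `function_id`, columns named
#'   by sample id; all values must be non-negative.
#' @param metadata a [sample_metadata()] table whose sample ids equal the
#'   column set of `values`.
#' @return object of class `stratified_table`: a list with elements
#'   `function_id`, `lineage`, `values`, `metadata`.
#' @export
stratified_table <- function(function_id, lineage, values, metadata) {
  function_id <- as.character(function_id)
  lineage <- as.character(lineage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(function_id) ||
      length(lineage) != length(function_id)) {
    stop("function_id, lineage and value rows must align")
  }
  if (is.null(colnames(values))) stop("value columns must be named by sample")
  if (!inherits(metadata, "sample_metadata")) {
    stop("metadata must be a sample_metadata table")
  }
  unknown <- setdiff(colnames(values), metadata$sample_id)
  if (length(unknown) > 0) {
    stop("unknown sample column(s): ", paste(unknown, collapse = ", "))
  }
  missing_s <- setdiff(metadata$sample_id, colnames(values))
  if (length(missing_s) > 0) {
    stop("sample(s) in metadata but not in table: ",
         paste(missing_s, collapse = ", "))
  }
  if (nrow(values) > 0) {
    neg <- which(values < 0, arr.ind = TRUE)
    if (nrow(neg) > 0) {
      stop("negative RPKM at row ", neg[1, 1], " ('", function_id[neg[1, 1]],
           "'), sample '", colnames(values)[neg[1, 2]], "'")
    }
    if (length(lineage) > 0) parse_lineage(lineage)  # validates format
    key <- paste(function_id, lineage, sep = "\r")
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1]
      stop("duplicate (function, lineage) row: ", function_id[d], " / ",
           lineage[d])
    }
  }
  values <- values[, metadata$sample_id, drop = FALSE]
  structure(list(function_id = function_id, lineage = lineage,
                 values = values, metadata = metadata),
            class = "stratified_table")
}

#' @export
print.stratified_table <- function(x, ...) {
  cat("stratified_table: ", nrow(x$values), " (function x lineage) rows, ",
      ncol(x$values), " samples, ",
      length(unique(x$metadata$treatment)), " treatments\n", sep = "")
  invisible(x)
}

#' @export
dim.stratified_table <- function(x) dim(x$values)

#' Read a stratified RPKM table from TSV
#'
#' Expected layout: tab-delimited with a header row; the first two columns
#' are `function_id` and `lineage` (canonical rank-prefixed, semicolon
#' delimited), remaining columns are samples matching the metadata.
#'
#' @param path file path.
#' @param metadata a [sample_metadata()] table; the file's sample columns
#'   must match its sample ids exactly.
#' @return a [stratified_table()].
#' @export
read_stratified_table <- function(path, metadata) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2 || !identical(names(df)[1:2], c("function_id", "lineage"))) {
    stop("first two columns must be 'function_id' and 'lineage'")
  }
  samp_cols <- names(df)[-(1:2)]
  vals <- matrix(0, nrow = nrow(df), ncol = length(samp_cols),
                 dimnames = list(NULL, samp_cols))
  for (j in seq_along(samp_cols)) {
    v <- suppressWarnings(as.numeric(df[[samp_cols[j]]]))
    bad <- which(is.na(v) & !is.na(df[[samp_cols[j]]]))
    if (length(bad) > 0) {
      stop("non-numeric value '", df[[samp_cols[j]]][bad[1]], "' at row ",
           bad[1], ", sample '", samp_cols[j], "'")
    }
    vals[, j] <- v
  }
  stratified_table(df$function_id, df$lineage, vals, metadata)
}

#' @rdname read_stratified_table
#' @param table a `stratified_table`.
#' @export
write_stratified_table <- function(table, path) {
  stopifnot(inherits(table, "stratified_table"))
  df <- data.frame(function_id = table$function_id, lineage = table$lineage,
                   table$values, stringsAsFactors = FALSE, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a stratified table over taxa
#'
#' Sums RPKM over all lineages sharing a function id, yielding the
#' unstratified (function-only) table. Each cell of the result equals the
#' taxon-sum of the parent table.
#'
#' @param table a [stratified_table()].
#' @return numeric matrix, rows = unique function ids (sorted by first
#'   appearance), columns = samples; carries attribute `metadata`.
#' @export
unstratify <- function(table) {
  stopifnot(inherits(table, "stratified_table"))
  ids <- unique(table$function_id)
  out <- rowsum(table$values, group = factor(table$function_id, levels = ids))
  out <- as.matrix(out)
  attr(out, "metadata") <- table$metadata
  out
}

#' Aggregate a table at a taxonomic rank
#'
#' Re-keys a stratified table so lineages are collapsed at the requested
#' rank (default genus, matching how the reference analysis reports
#' taxonomic contributions); RPKM values of merged rows are summed.
#'
#' @param table a [stratified_table()].
#' @param rank rank name to keep (all deeper ranks blanked).
#' @return a [stratified_table()] whose lineages are truncated at `rank`.
#' @export
aggregate_rank <- function(table, rank = "genus") {
  stopifnot(inherits(table, "stratified_table"))
  rank <- match.arg(rank, .RANKS)
  keep <- seq_len(match(rank, .RANKS))
  pl <- parse_lineage(table$lineage)
  for (r in .RANKS[-keep]) pl[[r]] <- ""
  lin <- do.call(make_lineage, setNames(as.list(pl),
                 c("domain", "phylum", "class_", "order_", "family_",
                   "genus", "species")))
  key <- paste(table$function_id, lin, sep = "\r")
  ord <- !duplicated(key)
  vals <- rowsum(table$values, group = factor(key, levels = key[ord]))
  stratified_table(table$function_id[ord], lin[ord], as.matrix(vals),
                   table$metadata)
}
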