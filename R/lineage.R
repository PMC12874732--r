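#' Build canonical lineage strings
#'
#' Lineages are represented throughout the package as rank-prefixed,
#' semicolon-delimited strings of the form
#' `d__Bacteria;p__...;c__...;o__...;f__...;g__...;s__...`, matching common
#' classifier exports. Missing ranks are kept in place with an empty name
#' after the prefix (e.g. `s__`), so genus and phylum extraction is always
#' positional by prefix, never by guessing.
#'
#' @param domain,phylum,class_,order_,family_,genus,species character vectors
#'   (recycled); use `""` or `NA` for an unassigned rank.
#' @return character vector of canonical lineage strings.
#' @examples
#' make_lineage(domain = "Bacteria", genus = "Pseudomonas",
#'              species = "Pseudomonas putida")
#' @export
make_lineage <- function(domain = "", phylum = "", class_ = "", order_ = "",
                         family_ = "", genus = "", species = "") {
  parts <- list(domain, phylum, class_, order_, family_, genus, species)
  parts <- lapply(parts, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  n <- max(lengths(parts))
  parts <- lapply(parts, rep_len, n)
  out <- mapply(function(...) {
    paste0(.RANK_PREFIX, c(...), collapse = ";")
  }, parts[[1]], parts[[2]], parts[[3]], parts[[4]], parts[[5]], parts[[6]],
     parts[[7]], USE.NAMES = FALSE)
  out
}

#' Parse lineage strings into a rank table
#'
#' @param x character vector of canonical lineage strings (see
#'   [make_lineage()]).
#' @return data.frame with one column per rank (domain ... species); an
#'   unassigned rank is the empty string.
#' @export
parse_lineage <- function(x) {
  stopifnot(is.character(x))
  fields <- strsplit(x, ";", fixed = TRUE)
  bad <- which(lengths(fields) != length(.RANKS))
  if (length(bad) > 0) {
    stop("malformed lineage string (expected ", length(.RANKS),
         " ';'-separated ranks) at position ", bad[1], ": ", x[bad[1]])
  }
  m <- do.call(rbind, fields)
  for (i in seq_along(.RANKS)) {
    pre <- .RANK_PREFIX[i]
    bad <- which(!startsWith(m[, i], pre))
    if (length(bad) > 0) {
      stop("lineage rank ", i, " does not start with '", pre,
           "' at position ", bad[1], ": ", x[bad[1]])
    }
    m[, i] <- substring(m[, i], nchar(pre) + 1L)
  }
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- .RANKS
  out
}

#' Extract a single rank from lineage strings
#'
#' @param x character vector of canonical lineage strings.
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @param unassigned value returned for a rank that is present but empty.
#' @return character vector of taxon names at that rank.
#' @export
lineage_rank <- function(x, rank, unassigned = .UNASSIGNED) {
  rank <- match.arg(rank, .RANKS)
  v <- parse_lineage(x)[[rank]]
  v[v == ""] <- unassigned
  v
}

#' @rdname lineage_rank
#' @export
lineage_genus <- function(x, unassigned = .UNASSIGNED) {
  lineage_rank(x, "genus", unassigned)
}

#' @rdname lineage_rank
#' @export
lineage_phylum <- function(x, unassigned = .UNASSIGNED) {
  lineage_rank(x, "phylum", unassigned)
}

#' @rdname lineage_rank
#' @export
lineage_species <- function(x, unassigned = .UNASSIGNED) {
  lineage_rank(x, "species", unassigned)
}
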