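#' Construct and validate a sample metadata table
#'
#' The experimental design behind most of the package is a one-factor layout:
#' each sample belongs to exactly one treatment group and carries a replicate
#' number. The reference design has 7 groups (5 organic-amendment treatments
#' plus unamended controls and natural reference soils) with 3 replicates
#' each, 21 samples in total.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param treatment character vector of treatment labels, one per sample.
#' @param replicate positive integer vector, one per sample.
#' @return data.frame of class `sample_metadata` with columns `sample_id`,
#'   `treatment`, `replicate`.
#' @export
sample_metadata <- function(sample_id, treatment, replicate) {
  sample_id <- as.character(sample_id)
  treatment <- as.character(treatment)
  replicate <- as.integer(replicate)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  if (length(treatment) != length(sample_id) ||
      length(replicate) != length(sample_id)) {
    stop("sample_id, treatment and replicate must have equal length")
  }
  if (any(is.na(treatment)) || any(treatment == "")) {
    stop("every sample needs a non-empty treatment label")
  }
  if (any(is.na(replicate)) || any(replicate < 1L)) {
    stop("replicate must be a small positive integer")
  }
  out <- data.frame(sample_id = sample_id, treatment = treatment,
                    replicate = replicate, stringsAsFactors = FALSE)
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' The reference 7-group x 3-replicate design
#'
#' Treatments: Natural (undisturbed reference soil), Control (unamended),
#' COVG (garden-waste compost), COHort (horticultural compost), SS (sewage
#' sludge), and the two 50:50 blends COVG+SS and COHort+SS.
#'
#' @param replicates replicates per treatment (default 3).
#' @return a `sample_metadata` table with `7 * replicates` samples named
#'   `<treatment>_r<replicate>` (treatment part with `+` replaced by `.`).
#' @export
reference_design <- function(replicates = 3L) {
  trts <- c("Natural", "Control", "COVG", "COHort", "SS", "COVG+SS",
            "COHort+SS")
  treatment <- rep(trts, each = replicates)
  replicate <- rep(seq_len(replicates), times = length(trts))
  ids <- paste0(gsub("+", ".", treatment, fixed = TRUE), "_r", replicate)
  sample_metadata(ids, treatment, replicate)
}

#' Read / write sample metadata TSV
#'
#' Tab-delimited, UTF-8, columns `sample_id`, `treatment`, `replicate`.
#'
#' @param path file path.
#' @return `read_sample_metadata` returns a `sample_metadata` table.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "treatment", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("metadata file missing column(s): ", paste(miss, collapse = ", "))
  }
  sample_metadata(df$sample_id, df$treatment, df$replicate)
}

#' @rdname read_sample_metadata
#' @param metadata a `sample_metadata` table.
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a per-sample soil-properties table
#'
#' Numeric physical/chemical/biochemical measurements per sample (electrical
#' conductivity, pH, total organic carbon, total nitrogen, available
#' phosphorus, water-holding capacities, basal respiration, enzyme
#' activities, bacterial fatty acids, ...). These are consumed only by the
#' correlation screen; missing values are explicit `NA` and are excluded
#' pairwise there.
#'
#' @param sample_id character vector of sample ids.
#' @param ... named numeric vectors, one per property.
#' @return data.frame of class `soil_properties`.
#' @export
soil_properties <- function(sample_id, ...) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in soil properties")
  cols <- list(...)
  if (length(cols) == 0) stop("at least one property column required")
  if (is.null(names(cols)) || any(names(cols) == "")) {
    stop("all property columns must be named")
  }
  for (nm in names(cols)) {
    if (!is.numeric(cols[[nm]])) stop("property '", nm, "' is not numeric")
    if (length(cols[[nm]]) != length(sample_id)) {
      stop("property '", nm, "' length does not match sample_id")
    }
  }
  out <- data.frame(sample_id = sample_id, cols, stringsAsFactors = FALSE,
                    check.names = FALSE)
  class(out) <- c("soil_properties", "data.frame")
  out
}

#' @rdname soil_properties
#' @param path file path of a TSV with a `sample_id` column and numeric
#'   property columns; missing values written/read as `NA`.
#' @export
read_soil_properties <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = "NA")
  if (!"sample_id" %in% names(df)) stop("soil-properties file needs sample_id")
  do.call(soil_properties,
          c(list(sample_id = df$sample_id),
            as.list(df[setdiff(names(df), "sample_id")])))
}

#' @rdname soil_properties
#' @param properties a `soil_properties` table.
#' @export
write_soil_properties <- function(properties, path) {
  write.table(properties, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
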