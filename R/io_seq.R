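# FASTA/FASTQ plumbing. Parsing is delegated to Biostrings; the wrappers
# only convert to/from plain R structures and add record-level validation
# errors where Biostrings' messages are opaque.

#' Read and write FASTA
#'
#' @param path file path.
#' @return `read_fasta` returns a data.frame with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  data.frame(id = names(set), seq = as.character(set),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta
#' @param records data.frame with columns `id`, `seq`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read and write FASTQ (Sanger quality encoding)
#'
#' @param path file path.
#' @return `read_fastq` returns a data.frame with columns `id`, `seq`,
#'   `qual`.
#' @export
read_fastq <- function(path) {
  # structural pre-check (4-line records): Biostrings does not validate
  # that quality length matches sequence length
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ '", path, "': line count not a multiple of 4")
  }
  n_rec <- length(lines) / 4
  for (i in seq_len(n_rec)) {
    off <- (i - 1) * 4
    if (!startsWith(lines[off + 1], "@") ||
        !startsWith(lines[off + 3], "+") ||
        nchar(lines[off + 2]) != nchar(lines[off + 4])) {
      stop("malformed FASTQ '", path, "' at record ", i,
           ": bad structure or sequence/quality lengths differ")
    }
  }
  parsed <- tryCatch({
    set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    list(set = set, qual = as.character(S4Vectors::mcols(set)$qualities))
  }, error = function(e) stop("malformed FASTQ '", path, "': ",
                              conditionMessage(e)))
  set <- parsed$set
  qual <- parsed$qual
  bad <- which(nchar(qual, type = "bytes") !=
                 nchar(as.character(set), type = "bytes"))
  if (length(bad) > 0) {
    stop("FASTQ record ", bad[1], " ('", names(set)[bad[1]],
         "'): sequence and quality lengths differ")
  }
  data.frame(id = names(set), seq = as.character(set), qual = qual,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @param records data.frame with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(records)))
  bad <- which(nchar(records$seq) != nchar(records$qual))
  if (length(bad) > 0) {
    stop("FASTQ record ", bad[1], " ('", records$id[bad[1]],
         "'): sequence and quality lengths differ")
  }
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- records$id
  q <- Biostrings::BStringSet(records$qual)
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = q)
  invisible(path)
}
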