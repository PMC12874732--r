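# Synthetic community, read and classifier-output simulators. A single
# global seed fans out to fixed per-stage substreams so a stage's output is
# reproducible even when upstream parameters change.

.stage_seed <- function(seed, stage) {
  offsets <- c(genomes = 11L, reads = 23L, classifier = 37L, rpkm = 53L,
               soil = 71L)
  s <- (as.integer(seed) %% 1000000000L) * 2L + offsets[[stage]]
  as.integer(s %% 2147483647L)
}

.local_seed <- function(seed) {
  # evaluate downstream RNG under `seed`, restoring the caller's stream
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  # restoration handled by caller via on.exit in exported functions
  invisible(old)
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate random genomes with a known genus/species hierarchy
#'
#' Sequences are i.i.d. bases at the requested GC fraction; genomes carry
#' deterministic lineages `GenusNN` / `GenusNN sp<M>` under a small set of
#' synthetic phyla. No gene structure is simulated: the genomes exist to
#' exercise read mapping and coverage arithmetic, not annotation.
#'
#' @param n_genera number of genera (>= 1).
#' @param species_per_genus species per genus (>= 1); each species gets one
#'   genome.
#' @param genome_length_bp genome length in bp (> 0).
#' @param gc_fraction target GC content in (0, 1).
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @param genus_prefix prefix for generated genus names (change it to keep
#'   phantom taxa disjoint from true taxa).
#' @return data.frame with columns `genome_id`, `lineage`, `length`, `seq`.
#' @export
generate_genomes <- function(n_genera, species_per_genus, genome_length_bp,
                             gc_fraction, seed,
                             genus_prefix = "Genus") {
  stopifnot(n_genera >= 1, species_per_genus >= 1)
  if (genome_length_bp <= 0) stop("genome_length_bp must be positive")
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0,1)")
  old <- .local_seed(.stage_seed(seed, "genomes"))
  on.exit(.restore_seed(old))
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
            (1 - gc_fraction) / 2)
  phyla <- paste0(genus_prefix, "Phylum", sprintf("%02d", 1:4))
  rows <- vector("list", n_genera * species_per_genus)
  k <- 0L
  for (g in seq_len(n_genera)) {
    genus <- paste0(genus_prefix, sprintf("%02d", g))
    phylum <- phyla[((g - 1L) %% length(phyla)) + 1L]
    for (s in seq_len(species_per_genus)) {
      species <- paste0(genus, " sp", s)
      seqc <- paste(sample(c("A", "C", "G", "T"), genome_length_bp,
                           replace = TRUE, prob = prob), collapse = "")
      k <- k + 1L
      rows[[k]] <- data.frame(
        genome_id = paste0(genus, "_sp", s),
        lineage = make_lineage(domain = "Bacteria", phylum = phylum,
                               genus = genus, species = species),
        length = genome_length_bp, seq = seqc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Assemble a community with known ground truth
#'
#' @param genomes data.frame from [generate_genomes()]: the taxa that truly
#'   shed reads.
#' @param metadata a [sample_metadata()] table.
#' @param phantom_genomes optional data.frame of additional genomes whose
#'   taxa are only ever misassignment targets; reads are never drawn from
#'   them, but their references exist so the coverage checker has something
#'   to map against (mirroring a real spurious call, where a reference
#'   exists but the reads do not belong to it). Must be disjoint from
#'   `genomes` at the species level.
#' @param abundance optional genomes x samples matrix of relative
#'   abundances (each column sums to 1); defaults to uniform.
#' @return object of class `community_truth`: list with `genomes`
#'   (true + phantom, with `is_phantom` flag), `abundance`, `phantom_taxa`
#'   (lineages).
#' @export
community_truth <- function(genomes, metadata, phantom_genomes = NULL,
                            abundance = NULL) {
  stopifnot(inherits(metadata, "sample_metadata"))
  n <- nrow(genomes)
  if (is.null(abundance)) {
    abundance <- matrix(1 / n, nrow = n, ncol = nrow(metadata),
                        dimnames = list(genomes$genome_id,
                                        metadata$sample_id))
  }
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundances must be non-negative")
  csum <- colSums(abundance)
  if (any(abs(csum - 1) > 1e-9)) {
    stop("per-sample abundances must sum to 1 (off in sample ",
         colnames(abundance)[which(abs(csum - 1) > 1e-9)[1]], ")")
  }
  phantom_taxa <- character(0)
  all_genomes <- cbind(genomes, is_phantom = FALSE)
  if (!is.null(phantom_genomes)) {
    shared <- intersect(lineage_species(genomes$lineage),
                        lineage_species(phantom_genomes$lineage))
    if (length(shared) > 0) {
      stop("phantom taxa overlap true taxa at species level: ",
           paste(shared, collapse = ", "))
    }
    phantom_taxa <- phantom_genomes$lineage
    all_genomes <- rbind(all_genomes,
                         cbind(phantom_genomes, is_phantom = TRUE))
  }
  structure(list(genomes = all_genomes, abundance = abundance,
                 metadata = metadata, phantom_taxa = phantom_taxa),
            class = "community_truth")
}

#' Simulate shotgun reads with a substitution error model
#'
#' Read start positions are uniform over the valid positions of the sampled
#' genome (both strands); each base is substituted independently at the
#' stated rate (no indels). Qualities are constant Sanger `I` (Q40), since
#' no downstream step consumes quality values.
#'
#' @param community a [community_truth()].
#' @param depth_per_sample reads per sample: a single number or a named
#'   vector over sample ids.
#' @param read_length read length (<= shortest genome).
#' @param substitution_rate per-base substitution probability in \[0, 1).
#' @param seed integer seed.
#' @return list with `reads` (data.frame `id`, `seq`, `qual`, `sample_id`)
#'   and `truth` (data.frame `read_id`, `sample_id`, `genome_id`, `start`,
#'   `end` 0-based half-open on the forward strand, `strand`, `n_errors`).
#' @export
simulate_reads <- function(community, depth_per_sample, read_length,
                           substitution_rate, seed) {
  stopifnot(inherits(community, "community_truth"))
  if (substitution_rate < 0 || substitution_rate >= 1) {
    stop("substitution_rate must be in [0, 1)")
  }
  genomes <- community$genomes[!community$genomes$is_phantom, , drop = FALSE]
  if (read_length > min(genomes$length)) {
    stop("read_length exceeds the shortest genome")
  }
  samples <- community$metadata$sample_id
  depth <- if (length(depth_per_sample) == 1) {
    setNames(rep(depth_per_sample, length(samples)), samples)
  } else depth_per_sample[samples]
  if (any(is.na(depth))) stop("depth_per_sample missing some samples")
  old <- .local_seed(.stage_seed(seed, "reads"))
  on.exit(.restore_seed(old))

  out_reads <- vector("list", length(samples))
  out_truth <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    sm <- samples[si]
    n <- as.integer(depth[sm])
    if (n == 0) {
      next
    }
    gi <- sample.int(nrow(genomes), n, replace = TRUE,
                     prob = community$abundance[genomes$genome_id, sm])
    glen <- genomes$length[gi]
    start0 <- pmin(floor(runif(n) * (glen - read_length + 1)),
                   glen - read_length)  # 0-based
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genomes$seq[gi], start0 + 1, start0 + read_length)
    nerr <- integer(n)
    if (substitution_rate > 0) {
      # per-base independent substitution; erroneous bases get a uniform
      # draw from the three other bases (cyclic shift by 1..3)
      mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE),
                           use.names = FALSE), nrow = n, byrow = TRUE)
      err <- which(matrix(runif(n * read_length) < substitution_rate,
                          n, read_length), arr.ind = TRUE)
      if (nrow(err) > 0) {
        bases <- c("A", "C", "G", "T")
        shift <- sample.int(3, nrow(err), replace = TRUE)
        mat[err] <- bases[((match(mat[err], bases) - 1L + shift) %% 4L) + 1L]
        nerr <- tabulate(err[, 1], nbins = n)
        seqs <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
      }
    }
    minus <- strand == "-"
    if (any(minus)) {
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
    }
    ids <- paste0(sm, "_read", seq_len(n))
    out_reads[[si]] <- data.frame(
      id = ids, seq = seqs, qual = strrep("I", read_length),
      sample_id = sm, stringsAsFactors = FALSE)
    out_truth[[si]] <- data.frame(
      read_id = ids, sample_id = sm, genome_id = genomes$genome_id[gi],
      start = as.integer(start0), end = as.integer(start0 + read_length),
      strand = strand, n_errors = nerr, stringsAsFactors = FALSE)
  }
  empty_reads <- data.frame(id = character(0), seq = character(0),
                            qual = character(0), sample_id = character(0),
                            stringsAsFactors = FALSE)
  empty_truth <- data.frame(read_id = character(0), sample_id = character(0),
                            genome_id = character(0), start = integer(0),
                            end = integer(0), strand = character(0),
                            n_errors = integer(0), stringsAsFactors = FALSE)
  reads_df <- do.call(rbind, out_reads)
  truth_df <- do.call(rbind, out_truth)
  list(reads = if (is.null(reads_df)) empty_reads else reads_df,
       truth = if (is.null(truth_df)) empty_truth else truth_df)
}

#' Simulate classifier output with planted misassignment
#'
#' Emulates a taxonomic classifier's per-read species calls: each read is,
#' independently with probability `misassignment_rate`, reassigned to a
#' phantom species chosen uniformly; otherwise it is labelled with its true
#' source species. The truth of every call is recorded so recovery can be
#' scored downstream.
#'
#' @param read_truth the `truth` component of [simulate_reads()].
#' @param community the [community_truth()] the reads came from.
#' @param misassignment_rate probability in \[0, 1\] of a planted wrong call.
#' @param seed integer seed.
#' @return data.frame of class `assignment_table`: `read_id`, `sample_id`,
#'   `lineage` (assigned, species level), `true_lineage`, `misassigned`.
#' @export
simulate_classifier_output <- function(read_truth, community,
                                       misassignment_rate, seed) {
  stopifnot(inherits(community, "community_truth"))
  if (misassignment_rate < 0 || misassignment_rate > 1) {
    stop("misassignment_rate must be in [0, 1]")
  }
  if (misassignment_rate > 0 && length(community$phantom_taxa) == 0) {
    stop("misassignment_rate > 0 requires a non-empty phantom taxon set")
  }
  true_lin <- community$genomes$lineage[
    match(read_truth$genome_id, community$genomes$genome_id)]
  old <- .local_seed(.stage_seed(seed, "classifier"))
  on.exit(.restore_seed(old))
  n <- nrow(read_truth)
  mis <- if (misassignment_rate > 0) {
    runif(n) < misassignment_rate
  } else rep(FALSE, n)
  assigned <- true_lin
  if (any(mis)) {
    assigned[mis] <- sample(community$phantom_taxa, sum(mis), replace = TRUE)
  }
  out <- data.frame(read_id = read_truth$read_id,
                    sample_id = read_truth$sample_id,
                    lineage = assigned, true_lineage = true_lin,
                    misassigned = mis, stringsAsFactors = FALSE)
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Write / read a classifier assignment table
#'
#' TSV with columns `read_id`, `sample_id`, `lineage` (canonical lineage
#' string at species level); the synthetic truth columns are kept when
#' present.
#'
#' @param assignments an `assignment_table` (or compatible data.frame).
#' @param path file path.
#' @export
write_assignments <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("read_id", "sample_id", "lineage")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("assignment table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- tapply(df$read_id, df$sample_id, anyDuplicated)
  if (any(unlist(bad) > 0)) stop("duplicate read_id within a sample")
  class(df) <- c("assignment_table", "data.frame")
  df
}
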