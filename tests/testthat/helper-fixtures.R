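# Small in-code fixtures shared across test files.

tiny_metadata <- function(treatments = c("A", "B"), replicates = 3L) {
  treatment <- rep(treatments, each = replicates)
  replicate <- rep(seq_len(replicates), length(treatments))
  sample_metadata(paste0(treatment, replicate), treatment, replicate)
}

# stratified table with explicit values: rows named "<ec>|<genus>"
tiny_table <- function(rows, values, metadata) {
  parts <- strsplit(rows, "|", fixed = TRUE)
  ec <- vapply(parts, `[`, "", 1)
  genus <- vapply(parts, `[`, "", 2)
  values <- matrix(values, nrow = length(rows),
                   dimnames = list(NULL, metadata$sample_id))
  stratified_table(ec, make_lineage(domain = "Bacteria", genus = genus),
                   values, metadata)
}

tiny_panel <- function() {
  pathway_panel("toy", data.frame(
    gene = c("geneA", "geneA", "geneB", "geneC"),
    ec = c("1.1.1.1", "1.1.1.2", "2.2.2.2", "3.3.3.3"),
    process = c("procX", "procX", "procX", "procY"),
    stringsAsFactors = FALSE))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# exhaustive sliding-window ungapped-alignment oracle for map_reads:
# tries every diagonal on both strands, full-length clipped alignment
oracle_map <- function(read, genome, min_identity = 0.90,
                       min_aligned_fraction = 0.80) {
  glen <- nchar(genome)
  rlen <- nchar(read)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  gch <- utf8ToInt(genome)
  for (r in c(read, rc)) {
    rch <- utf8ToInt(r)
    for (a in seq(1 - rlen + 1, glen)) {     # alignment start, 1-based
      b1 <- max(1, a)
      b2 <- min(glen, a + rlen - 1)
      al <- b2 - b1 + 1
      if (al < min_aligned_fraction * rlen) next
      hits <- sum(rch[(b1 - a + 1):(b2 - a + 1)] == gch[b1:b2])
      if (hits >= min_identity * al) return(TRUE)
    }
  }
  FALSE
}

# brute-force PERMANOVA oracle: enumerate every distinct relabeling
# (unordered equal-size group swaps deduplicated via canonical form) and
# compute pseudo-F by naive double loops, independently of the package.
oracle_permanova_p <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- factor(groups)
  f_stat <- function(lab) {
    lv <- unique(lab)
    sst <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
    sst <- sst / n
    ssw <- 0
    for (g in lv) {
      ix <- which(lab == g)
      if (length(ix) > 1) {
        s <- 0
        for (i in ix) for (j in ix) s <- s + d[i, j]^2
        ssw <- ssw + s / (2 * length(ix))
      }
    }
    ssa <- sst - ssw
    if (ssw <= 0) return(Inf)
    (ssa / (length(lv) - 1)) / (ssw / (n - length(lv)))
  }
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  labs <- as.integer(groups)
  sizes <- table(labs)
  canon <- function(lab) {
    # relabel: among equal-size groups, ids by order of first occurrence
    out <- integer(length(lab))
    seen <- list()
    for (sz in unique(as.integer(sizes))) {
      gids <- as.integer(names(sizes))[as.integer(sizes) == sz]
      firsts <- vapply(gids, function(g) which(lab == g)[1], 0L)
      for (k in seq_along(gids)) {
        out[lab == gids[order(firsts)][k]] <- gids[k]
      }
    }
    out
  }
  seqs <- unique(vapply(all_perms(labs), function(p)
    paste(canon(p), collapse = ","), ""))
  f_obs <- f_stat(labs)
  f_all <- vapply(strsplit(seqs, ","), function(s)
    f_stat(as.integer(s)), numeric(1))
  list(p = mean(f_all >= f_obs - 1e-12), n_distinct = length(seqs))
}
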