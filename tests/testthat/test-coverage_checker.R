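test_that("read pooling unions replicates within a treatment", {
  md <- tiny_metadata(c("T1", "T2"), 3L)
  lin_x <- make_lineage(domain = "Bacteria", genus = "Gx",
                        species = "Gx sp1")
  lin_y <- make_lineage(domain = "Bacteria", genus = "Gy",
                        species = "Gy sp1")
  asn <- data.frame(
    read_id = paste0("r", 1:40),
    sample_id = c(rep(c("T11", "T12", "T13"), each = 10), rep("T11", 10)),
    lineage = c(rep(lin_x, 30), rep(lin_y, 10)),
    stringsAsFactors = FALSE)
  pools <- pool_reads_by_taxon(asn, md)
  px <- pools[pools$lineage == lin_x & pools$treatment == "T1", ]
  expect_identical(px$n_assigned, 30L)              # 3 x 10 pooled
  expect_identical(nrow(pools), 2L)                 # no empty T2 pools
  # disjoint pools conserve the sample's read count
  expect_identical(sum(pools$n_assigned), 40L)
  expect_error(pool_reads_by_taxon(
    data.frame(read_id = "r", sample_id = "nope", lineage = lin_x), md),
    "missing from metadata")
})

test_that("exact substrings map home; random reads never map", {
  set.seed(21)
  genome <- random_dna(5000)
  reads <- c(r1 = substr(genome, 101, 200))
  m <- map_reads(reads, genome)
  expect_true(m$confirmed[1])
  expect_identical(m$start[1], 100L)
  expect_identical(m$end[1], 200L)

  # reverse-strand read reported in forward coordinates
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(genome, 301, 400))))
  m2 <- map_reads(c(r = rc), genome)
  expect_true(m2$confirmed[1])
  expect_identical(m2$start[1], 300L)

  # 1000 reads generated independently of the genome: zero confirmations
  rnd <- vapply(1:1000, function(i) random_dna(100), "")
  names(rnd) <- paste0("x", 1:1000)
  m3 <- map_reads(rnd, genome)
  expect_identical(sum(m3$confirmed), 0L)

  expect_identical(nrow(map_reads(character(0), genome)), 0L)
})

test_that("mapper decisions agree with the exhaustive alignment oracle", {
  set.seed(31)
  genome <- random_dna(2000)
  k <- 31L
  cases <- list()
  for (i in 1:40) {
    start <- sample(1:(2000 - 100), 1)
    read <- substr(genome, start, start + 99)
    n_mut <- sample(0:12, 1)
    if (n_mut > 0) {
      # keep the first seed k-mer clean so the heuristic seed always fires
      pos <- sample((k + 1):100, n_mut)
      s <- strsplit(read, "")[[1]]
      for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
      read <- paste(s, collapse = "")
    }
    cases[[i]] <- read
  }
  reads <- setNames(unlist(cases), paste0("c", 1:40))
  m <- map_reads(reads, genome)
  oracle <- vapply(reads, oracle_map, TRUE, genome = genome)
  expect_identical(m$confirmed, unname(oracle))
  # a read with exactly 5% substitutions passes the 0.90 identity cutoff
  r5 <- strsplit(substr(genome, 501, 600), "")[[1]]
  for (p in c(40, 55, 70, 85, 99)) {
    r5[p] <- setdiff(c("A", "C", "G", "T"), r5[p])[1]
  }
  r5 <- paste(r5, collapse = "")
  expect_true(oracle_map(r5, genome))
  expect_true(map_reads(c(r5 = r5), genome)$confirmed)
})

test_that("mapper never confirms what the oracle rejects", {
  set.seed(32)
  genome <- random_dna(1500)
  reads <- c(
    vapply(1:30, function(i) {        # heavily mutated substrings
      start <- sample(1:(1500 - 100), 1)
      r <- strsplit(substr(genome, start, start + 99), "")[[1]]
      pos <- sample(100, 25)
      for (p in pos) r[p] <- setdiff(c("A", "C", "G", "T"), r[p])[1]
      paste(r, collapse = "")
    }, ""),
    vapply(1:30, function(i) random_dna(100), ""))
  names(reads) <- paste0("n", seq_along(reads))
  m <- map_reads(reads, genome)
  oracle <- vapply(reads, oracle_map, TRUE, genome = genome)
  expect_true(all(!m$confirmed | oracle))
})

test_that("breadth of coverage is interval-union arithmetic", {
  expect_equal(breadth_of_coverage(cbind(0, 100), 1000), 0.1)
  expect_equal(breadth_of_coverage(rbind(c(0, 100), c(0, 100)), 1000), 0.1)
  expect_equal(breadth_of_coverage(rbind(c(0, 100), c(50, 150)), 1000),
               0.15)
  expect_equal(breadth_of_coverage(matrix(numeric(0), ncol = 2), 1000), 0)
  expect_error(breadth_of_coverage(cbind(900, 1100), 1000), "out of bounds")

  # order/duplication invariance and monotonicity under added reads
  set.seed(5)
  iv <- cbind(s <- sample(0:900, 50), s + sample(10:100, 50, TRUE))
  b1 <- breadth_of_coverage(iv, 1000)
  expect_equal(breadth_of_coverage(iv[sample(50), ], 1000), b1)
  expect_equal(breadth_of_coverage(rbind(iv, iv), 1000), b1)
  prev <- 0
  for (n in c(10, 20, 30, 40, 50)) {
    b <- breadth_of_coverage(iv[1:n, , drop = FALSE], 1000)
    expect_gte(b, prev)
    prev <- b
  }
})

test_that("genus decision rule: clauses, boundaries and rule modes", {
  mk <- function(breadth, reads, conf, genus = "Gx", sp = "sp1",
                 treatment = "T1") {
    data.frame(lineage = make_lineage(domain = "Bacteria", genus = genus,
                                      species = paste(genus, sp)),
               treatment = treatment, n_assigned = reads,
               confirmed_fraction = conf, breadth = breadth,
               stringsAsFactors = FALSE)
  }
  expect_identical(flag_genera(mk(0.02, 10, 0.2))$flag, "confirmed")
  expect_identical(flag_genera(mk(0.005, 150, 0.6))$flag, "confirmed")
  expect_identical(flag_genera(mk(0.005, 150, 0.4))$flag,
                   "potentially_spurious")
  expect_identical(flag_genera(mk(0.01, 0, 0))$flag, "confirmed")  # boundary
  expect_identical(flag_genera(mk(0.005, 100, 0.5))$flag, "confirmed")
  expect_error(flag_genera(mk(0.02, 10, 0.2)[0, ]), "empty")

  # any- vs all-species: one passing and one failing species in a genus
  two <- rbind(mk(0.02, 10, 0.2, sp = "sp1"), mk(0, 10, 0, sp = "sp2"))
  expect_identical(flag_genera(two, rule_mode = "any_species")$flag,
                   "confirmed")
  expect_identical(flag_genera(two, rule_mode = "all_species")$flag,
                   "potentially_spurious")

  # raising thresholds never rescues a flagged genus (rule monotonicity)
  sc <- rbind(mk(0.02, 120, 0.6), mk(0.003, 150, 0.55, genus = "Gy"))
  base_flags <- flag_genera(sc)$flag
  for (th in list(coverage_thresholds(breadth_min = 0.05),
                  coverage_thresholds(reads_min = 200),
                  coverage_thresholds(confirmed_min = 0.9))) {
    harder <- flag_genera(sc, th)$flag
    expect_true(all(!(base_flags == "potentially_spurious" &
                        harder == "confirmed")))
  }
})

test_that("verify composes the pipeline and reports unverifiable species", {
  md <- tiny_metadata(c("T1", "T2"), 2L)
  gen <- generate_genomes(4, 1, 4000, 0.5, seed = 1)
  comm <- community_truth(gen, md)
  sim <- simulate_reads(comm, 400, 100, 0.01, seed = 2)
  asn <- simulate_classifier_output(sim$truth, comm, 0, seed = 3)
  rep <- verify(asn, comm$genomes, sim$reads, md)
  # no misassignment + ample depth: nothing flagged
  expect_true(all(rep$genus_verdicts$flag == "confirmed"))
  expect_true(all(rep$species_coverage$status == "verified"))
  # n_confirmed <= n_assigned and breadth bounded by confirmed bases
  sc <- rep$species_coverage
  expect_true(all(sc$n_confirmed <= sc$n_assigned))
  expect_true(all(sc$breadth * sc$genome_length <= sc$n_confirmed * 100))

  # a species with no reference genome is reported, never dropped
  rep2 <- verify(asn, comm$genomes[-1, ], sim$reads, md)
  missing_sp <- lineage_species(comm$genomes$lineage[1])
  rows <- rep2$species_coverage[
    lineage_species(rep2$species_coverage$lineage) == missing_sp, ]
  expect_true(nrow(rows) > 0)
  expect_true(all(rows$status == "unverifiable"))
  expect_false(lineage_genus(comm$genomes$lineage[1]) %in%
                 rep2$genus_verdicts$genus)
})

test_that("sub-1% breadths are annotated against the 0.1% fallback", {
  # two non-overlapping 100 bp reads on a 100 kb genome: breadth 0.002,
  # covered_bases 200 -- above the 0.1% trace annotation, below the 1%
  # pass cutoff, and too few reads for the rescue clause
  md <- sample_metadata("s1", "T1", 1)
  gen <- generate_genomes(1, 1, 100000, 0.5, seed = 8)
  reads <- data.frame(
    id = c("r1", "r2"),
    seq = c(substr(gen$seq, 1001, 1100), substr(gen$seq, 5001, 5100)),
    sample_id = "s1", stringsAsFactors = FALSE)
  asn <- data.frame(read_id = reads$id, sample_id = "s1",
                    lineage = gen$lineage, stringsAsFactors = FALSE)
  rep <- verify(asn, gen, reads, md)
  sc <- rep$species_coverage
  expect_equal(sc$breadth, 0.002, tolerance = 1e-12)
  expect_equal(sc$covered_bases, 200)
  expect_true(sc$exceeds_fallback)
  expect_false(sc$pass)
  expect_identical(rep$genus_verdicts$flag, "potentially_spurious")
})
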