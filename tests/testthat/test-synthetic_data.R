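test_that("genome generation is deterministic with the stated GC", {
  g1 <- generate_genomes(2, 2, 10000, 0.5, seed = 7)
  g2 <- generate_genomes(2, 2, 10000, 0.5, seed = 7)
  expect_identical(g1, g2)
  expect_identical(nrow(g1), 4L)
  expect_true(all(nchar(g1$seq) == 10000))
  expect_identical(length(unique(lineage_genus(g1$lineage))), 2L)

  # GC recovery: binomial s.d. at n = 1e5 is ~0.0016; 0.01 is > 6 sigma
  g3 <- generate_genomes(1, 1, 100000, 0.7, seed = 3)
  gc <- sum(strsplit(g3$seq, "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.7), 0.01)

  expect_error(generate_genomes(1, 1, -5, 0.5, seed = 1), "positive")
  expect_error(generate_genomes(1, 1, 100, 1.2, seed = 1), "gc_fraction")
})

test_that("simulated reads match their source intervals and error model", {
  md <- tiny_metadata()
  gen <- generate_genomes(3, 1, 5000, 0.5, seed = 1)
  comm <- community_truth(gen, md)

  # error-free reads are exact (strand-aware) substrings of their genome
  sim0 <- simulate_reads(comm, 50, 80, 0, seed = 2)
  expect_identical(nrow(sim0$reads), 6L * 50L)
  for (i in sample.int(nrow(sim0$truth), 20)) {
    tr <- sim0$truth[i, ]
    src <- substr(gen$seq[gen$genome_id == tr$genome_id],
                  tr$start + 1, tr$end)
    obs <- sim0$reads$seq[sim0$reads$id == tr$read_id]
    if (tr$strand == "-") {
      obs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(obs)))
    }
    expect_identical(obs, src)
  }
  # truth intervals lie inside the genome, 0-based half-open
  expect_true(all(sim0$truth$start >= 0))
  expect_true(all(sim0$truth$end <= 5000))
  expect_true(all(sim0$truth$end - sim0$truth$start == 80))

  # binomial error count: mean 1.0 +/- 0.03 (3 sigma at 10000 reads)
  md1 <- sample_metadata("s1", "T", 1)
  comm1 <- community_truth(gen[1, ], md1)
  sim1 <- simulate_reads(comm1, 10000, 100, 0.01, seed = 4)
  expect_lt(abs(mean(sim1$truth$n_errors) - 1.0), 0.03)
  # errors are real substitutions: hamming distance equals n_errors
  for (i in sample.int(10000, 10)) {
    tr <- sim1$truth[i, ]
    src <- substr(gen$seq[1], tr$start + 1, tr$end)
    obs <- sim1$reads$seq[i]
    if (tr$strand == "-") {
      obs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(obs)))
    }
    ham <- sum(utf8ToInt(obs) != utf8ToInt(src))
    expect_identical(ham, as.integer(tr$n_errors))
  }

  # depth 0 gives empty outputs without error
  sim_e <- simulate_reads(comm, 0, 80, 0, seed = 5)
  expect_identical(nrow(sim_e$reads), 0L)
})

test_that("classifier simulation plants misassignments at the stated rate", {
  md <- tiny_metadata()
  gen <- generate_genomes(3, 1, 2000, 0.5, seed = 1)
  ph <- generate_genomes(2, 1, 2000, 0.5, seed = 2, genus_prefix = "Ph")
  comm <- community_truth(gen, md, phantom_genomes = ph)
  sim <- simulate_reads(comm, 1700, 80, 0, seed = 3)  # ~10200 reads

  a0 <- simulate_classifier_output(sim$truth, comm, 0, seed = 4)
  expect_identical(a0$lineage, a0$true_lineage)

  a1 <- simulate_classifier_output(sim$truth, comm, 1, seed = 4)
  expect_true(all(a1$lineage %in% comm$phantom_taxa))

  a01 <- simulate_classifier_output(sim$truth, comm, 0.1, seed = 4)
  n <- nrow(a01)
  expect_lt(abs(sum(a01$misassigned) - 0.1 * n), 3 * sqrt(n * 0.1 * 0.9))

  comm_np <- community_truth(gen, md)
  expect_error(simulate_classifier_output(sim$truth, comm_np, 0.1, seed = 1),
               "phantom")
})

test_that("planted stratified tables obey the design exactly at sigma 0", {
  panel <- tiny_panel()
  des <- planted_design(
    treatments = c("Control", "SS"), replicates = 3L,
    gene_weights = c(geneA = 0.5, geneB = 0.3, geneC = 0.2),
    genus_weights = c(G1 = 1, G2 = 1),
    treatment_totals = c(Control = 100, SS = 100),
    gene_mult = list(SS = c(geneB = 2)), sigma = 0)
  out <- generate_stratified_rpkm(des, panel, seed = 1)
  v <- out$table$values
  md <- out$metadata
  ctrl <- md$sample_id[md$treatment == "Control"]
  ss <- md$sample_id[md$treatment == "SS"]
  # replicates identical at sigma 0
  expect_equal(v[, ctrl[1]], v[, ctrl[2]], tolerance = 0)
  # planted multiplier: SS geneB cells exactly 2x Control cells
  bix <- out$table$function_id == "2.2.2.2"
  expect_equal(v[bix, ss[1]], 2 * v[bix, ctrl[1]], tolerance = 1e-12)
  # other genes unchanged across equal-total treatments
  cix <- out$table$function_id == "3.3.3.3"
  expect_equal(v[cix, ss[1]], v[cix, ctrl[1]], tolerance = 1e-12)
  # planted total
  expect_equal(unname(sum(v[, ctrl[1]])), 100, tolerance = 1e-9)
})

test_that("zero-baseline genes stay exactly zero and drive detection", {
  n_panel <- load_pathway_panel("map00910")
  out <- generate_stratified_rpkm(default_n_design(sigma = 0.1), n_panel,
                                  seed = 3)
  expect_identical(
    unname(detected_function_count(out$table, n_panel)["n_detected"]), 32L)
  zero_genes <- names(which(default_n_design()$gene_weights == 0))
  zero_ecs <- n_panel$gene_map$ec[n_panel$gene_map$gene %in% zero_genes]
  expect_true(all(out$table$values[
    out$table$function_id %in% zero_ecs, ] == 0))

  p_panel <- load_pathway_panel("map00440")
  outp <- generate_stratified_rpkm(default_p_design(sigma = 0.1), p_panel,
                                   seed = 3)
  expect_identical(
    unname(detected_function_count(outp$table, p_panel)["n_detected"]), 17L)
})

test_that("planted effects are recoverable through replicate noise", {
  # multiplier 3 on one gene, sigma 0.1, 3 replicates: the treatment-vs-
  # control mean ratio should land in [2.5, 3.5] in >= 95% of seeds
  panel <- tiny_panel()
  des <- planted_design(
    treatments = c("Control", "SS"), replicates = 3L,
    gene_weights = c(geneA = 0.5, geneB = 0.3, geneC = 0.2),
    genus_weights = c(G1 = 1, G2 = 1),
    treatment_totals = c(Control = 100, SS = 100),
    gene_mult = list(SS = c(geneC = 3)), sigma = 0.1)
  hit <- 0L
  for (s in 1:100) {
    out <- generate_stratified_rpkm(des, panel, seed = s)
    md <- out$metadata
    cix <- out$table$function_id == "3.3.3.3"
    ratio <- mean(out$table$values[cix, md$treatment == "SS"]) /
      mean(out$table$values[cix, md$treatment == "Control"])
    if (ratio >= 2.5 && ratio <= 3.5) hit <- hit + 1L
  }
  expect_gte(hit, 95L)
})

test_that("soil-property generator plants exact means at zero noise", {
  md <- reference_design()
  eff <- default_soil_effects()
  sp <- generate_soil_properties(md, eff, 0, seed = 1)
  expect_equal(sp$pH[md$treatment == "SS"], rep(eff$pH[["SS"]], 3))
  # deterministic under seed
  sp2 <- generate_soil_properties(md, eff, 0.05, seed = 9)
  sp3 <- generate_soil_properties(md, eff, 0.05, seed = 9)
  expect_identical(sp2, sp3)
  # zero-noise planted linear relation with a gene's RPKM gives r = 1
  panel <- load_pathway_panel("map00910")
  out <- generate_stratified_rpkm(default_n_design(sigma = 0), panel,
                                  seed = 1)
  gt <- unstratify(out$table)
  glnA_row <- gt["6.3.1.2", , drop = FALSE]
  eff1 <- list(tracer = setNames(
    2 * vapply(unique(md$treatment), function(t)
      glnA_row[1, md$sample_id[md$treatment == t][1]], 0) + 5,
    unique(md$treatment)))
  sp4 <- generate_soil_properties(md, eff1, 0, seed = 2)
  scr <- correlation_screen(sp4, glnA_row, alpha = 0.05)
  expect_equal(scr$r[1], 1, tolerance = 1e-9)
})

test_that("seed fan-out keeps generator outputs byte-identical", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(generate_genomes(2, 1, 3000, 0.45, seed = 13)[
    c("genome_id", "seq")] |> setNames(c("id", "seq")), f1)
  write_fasta(generate_genomes(2, 1, 3000, 0.45, seed = 13)[
    c("genome_id", "seq")] |> setNames(c("id", "seq")), f2)
  expect_identical(readLines(f1), readLines(f2))
})
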