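# Planted-effect generator for stratified RPKM tables and soil properties.
# The defaults emulate the reference study conditions: a 7-treatment x
# 3-replicate soil design, pathway totals and gene shares matching the
# reported nitrogen and phosphonate profiles, and one planted dominant
# genus per treatment.

#' Describe a planted experimental design
#'
#' Cell values of the generated stratified table follow
#' `baseline(gene, genus) * multiplier(treatment) * boost(treatment, genus)
#'  * exp(N(0, sigma))` per replicate, where the baseline is the separable
#' product `gene_weights[g] * genus_weights[u]`, rescaled per treatment so
#' the expected per-sample pathway total equals `treatment_totals` (up to
#' the log-normal mean factor `exp(sigma^2/2)`). Because the baseline is
#' separable and boosts act uniformly on all genes of a genus, planted gene
#' shares equal `gene_weights` exactly in expectation. Genes with weight 0
#' stay exactly 0 ("not detected").
#'
#' @param treatments character vector of treatment labels.
#' @param replicates replicates per treatment.
#' @param gene_weights named non-negative numeric: relative share of total
#'   RPKM carried by each gene symbol (need not sum to 1; zero = absent).
#' @param genus_weights named positive numeric: relative genus abundances.
#' @param treatment_totals named numeric: expected per-sample pathway-total
#'   RPKM for each treatment.
#' @param genus_boost named list `treatment -> named numeric (genus ->
#'   multiplier)`; genera not listed get 1. Used to plant a dominant genus.
#' @param gene_mult named list `treatment -> named numeric (effect
#'   multiplier)` applied after the total normalisation, so a multiplier m
#'   on a gene makes that gene's cells exactly m times the corresponding
#'   cells of an unmultiplied treatment with equal planted total. Names are
#'   either a gene symbol (applies to all genera) or `"gene:genus"` for a
#'   single pair.
#' @param sigma log-normal replicate-noise sd (on the log scale).
#' @return object of class `planted_design`.
#' @export
planted_design <- function(treatments, replicates = 3L, gene_weights,
                           genus_weights, treatment_totals,
                           genus_boost = list(), gene_mult = list(),
                           sigma = 0.1) {
  stopifnot(length(treatments) >= 1, replicates >= 1)
  if (any(gene_weights < 0)) stop("gene_weights must be >= 0")
  if (any(genus_weights <= 0)) stop("genus_weights must be > 0")
  if (!all(treatments %in% names(treatment_totals))) {
    stop("treatment_totals must cover every treatment")
  }
  if (any(treatment_totals <= 0)) stop("treatment_totals must be > 0")
  for (t in names(genus_boost)) {
    if (!t %in% treatments) stop("genus_boost for unknown treatment: ", t)
    if (any(genus_boost[[t]] <= 0)) stop("boost multipliers must be > 0")
  }
  for (t in names(gene_mult)) {
    if (!t %in% treatments) stop("gene_mult for unknown treatment: ", t)
    if (any(gene_mult[[t]] <= 0)) stop("effect multipliers must be > 0")
  }
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(treatments = treatments, replicates = as.integer(replicates),
                 gene_weights = gene_weights, genus_weights = genus_weights,
                 treatment_totals = treatment_totals,
                 genus_boost = genus_boost, gene_mult = gene_mult,
                 sigma = sigma),
            class = "planted_design")
}

#' Reference planted designs for the packaged pathway panels
#'
#' `default_n_design()` mirrors the reported nitrogen-metabolism profile:
#' 7 of the 39 panel ECs absent (so 32 are detected), glnA carrying 47% of
#' total RPKM, gltBD 12%, gudB 5%, gdhA 4%, napAB and nosZ 2% each,
#' pmoABC-amoABC 4%, the remaining detected genes 1% each; per-sample
#' pathway totals per treatment of 520 (Natural), 541 (Control), 723
#' (COVG), 647 (COHort), 687 (SS), 549 (COVG+SS) and 759 (COHort+SS); and
#' one dominant genus planted per treatment (e.g. Streptomyces in
#' Control/Natural, Pseudomonas in SS). `default_p_design()` does the same
#' for phosphonate/phosphinate metabolism: 14 of 31 ECs absent (17
#' detected), phnJ 41%, phnW 20%, phnGHIL 12%, pmmS 7%, PPT 4%, and totals
#' of 31/33/38/46/38/52/69.
#'
#' @param sigma log-normal replicate-noise sd (default 0.1).
#' @return a [planted_design()].
#' @export
default_n_design <- function(sigma = 0.1) {
  heavy <- c(glnA = 0.47, gltBD = 0.12, gudB = 0.05, gdhA = 0.04,
             napAB = 0.02, nosZ = 0.02, `pmoABC-amoABC` = 0.04)
  absent <- c("hzsABC", "hdh", "vnfDKG", "nmo", "aspQ", "fmdA", "CPS1")
  panel <- load_pathway_panel("map00910")
  others <- setdiff(names(panel$process_map), c(names(heavy), absent))
  w <- c(heavy, setNames(rep(0.01, length(others)), others),
         setNames(rep(0, length(absent)), absent))
  genera <- c("Streptomyces", "Pseudomonas", "Nitrosospira", "Halomonas",
              "Mycobacterium", "Mesorhizobium", "Nocardioides",
              "Mycolicibacterium", "Stutzerimonas", "Luteimonas",
              "Skermanella", "Mycolicibacter")
  dominant <- c(Natural = "Streptomyces", Control = "Streptomyces",
                COVG = "Mycolicibacterium", COHort = "Mycobacterium",
                SS = "Pseudomonas", `COVG+SS` = "Halomonas",
                `COHort+SS` = "Mesorhizobium")
  totals <- c(Natural = 520, Control = 541, COVG = 723, COHort = 647,
              SS = 687, `COVG+SS` = 549, `COHort+SS` = 759)
  boost <- lapply(dominant, function(g) setNames(4, g))
  planted_design(names(totals), 3L, w,
                 setNames(rep(1, length(genera)), genera), totals,
                 genus_boost = boost, sigma = sigma)
}

#' @rdname default_n_design
#' @export
default_p_design <- function(sigma = 0.1) {
  heavy <- c(phnJ = 0.41, phnW = 0.20, phnGHIL = 0.12, pmmS = 0.07,
             PPT = 0.04)
  absent <- c("phnO", "phnP", "palA", "phnZ", "ptxD", "phpE", "phpJ",
              "phpK", "fom3", "frbG", "frbF", "pcs", "aept", "phnY")
  panel <- load_pathway_panel("map00440")
  others <- setdiff(names(panel$process_map), c(names(heavy), absent))
  w <- c(heavy, setNames(rep(0.16 / length(others), length(others)), others),
         setNames(rep(0, length(absent)), absent))
  genera <- c("Rhizobium", "Streptomyces", "Pseudomonas", "Mesorhizobium",
              "Sinorhizobium", "Bosea", "Burkholderia", "Halomonas",
              "Cohaesibacter", "Pseudorhizobium", "Devosia",
              "Bifidobacterium")
  dominant <- c(Natural = "Streptomyces", Control = "Mesorhizobium",
                COVG = "Sinorhizobium", COHort = "Rhizobium",
                SS = "Pseudomonas", `COVG+SS` = "Bosea",
                `COHort+SS` = "Rhizobium")
  totals <- c(Natural = 31, Control = 33, COVG = 38, COHort = 46, SS = 38,
              `COVG+SS` = 52, `COHort+SS` = 69)
  boost <- lapply(dominant, function(g) setNames(4, g))
  planted_design(names(totals), 3L, w,
                 setNames(rep(1, length(genera)), genera), totals,
                 genus_boost = boost, sigma = sigma)
}

#' Generate a stratified RPKM table with planted effects
#'
#' @param design a [planted_design()]; all its gene symbols must exist in
#'   the panel.
#' @param panel a [pathway_panel()]; a gene's RPKM is split equally across
#'   its panel ECs, so table rows are keyed by EC.
#' @param seed integer seed.
#' @return list with `table` (a [stratified_table()] with one row per
#'   (EC, genus)), `metadata`, and `truth` (expected cell means, planted
#'   gene shares, dominant genus per treatment where boosted).
#' @export
generate_stratified_rpkm <- function(design, panel, seed) {
  stopifnot(inherits(design, "planted_design"),
            inherits(panel, "pathway_panel"))
  unknown <- setdiff(names(design$gene_weights), names(panel$process_map))
  if (length(unknown) > 0) {
    stop("gene symbol(s) absent from panel: ", paste(unknown, collapse = ", "))
  }
  metadata <- {
    treatment <- rep(design$treatments, each = design$replicates)
    replicate <- rep(seq_len(design$replicates), length(design$treatments))
    sample_metadata(paste0(gsub("+", ".", treatment, fixed = TRUE), "_r",
                           replicate), treatment, replicate)
  }
  genera <- names(design$genus_weights)
  genes <- names(design$gene_weights)
  # rows: every (EC of gene, genus) pair, gene RPKM split across its ECs
  gm <- panel$gene_map[panel$gene_map$gene %in% genes, , drop = FALSE]
  n_ec <- table(gm$gene)
  rows <- expand.grid(ec_i = seq_len(nrow(gm)), genus = genera,
                      stringsAsFactors = FALSE)
  gene_r <- gm$gene[rows$ec_i]
  ec_r <- gm$ec[rows$ec_i]
  base <- design$gene_weights[gene_r] / as.numeric(n_ec[gene_r]) *
    design$genus_weights[rows$genus]

  # per-treatment expected cell means, normalised to the planted totals
  mu <- matrix(0, nrow = nrow(rows), ncol = nrow(metadata),
               dimnames = list(NULL, metadata$sample_id))
  for (t in design$treatments) {
    boost <- rep(1, nrow(rows))
    b <- if (t %in% names(design$genus_boost)) design$genus_boost[[t]]
    if (!is.null(b)) {
      hit <- rows$genus %in% names(b)
      boost[hit] <- b[rows$genus[hit]]
    }
    cell <- base * boost
    cell <- cell * design$treatment_totals[[t]] / sum(cell)
    gm_t <- if (t %in% names(design$gene_mult)) design$gene_mult[[t]]
    if (!is.null(gm_t)) {
      for (nm in names(gm_t)) {
        parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
        hit <- if (length(parts) == 2) {
          gene_r == parts[1] & rows$genus == parts[2]
        } else gene_r == nm
        if (!any(hit)) stop("gene_mult entry matches nothing: ", nm)
        cell[hit] <- cell[hit] * gm_t[[nm]]
      }
    }
    for (sm in metadata$sample_id[metadata$treatment == t]) {
      mu[, sm] <- cell
    }
  }
  old <- .local_seed(.stage_seed(seed, "rpkm"))
  on.exit(.restore_seed(old))
  noise <- if (design$sigma > 0) {
    matrix(exp(rnorm(length(mu), 0, design$sigma)), nrow = nrow(mu))
  } else 1
  vals <- mu * noise
  vals[mu == 0] <- 0  # absent functions stay exactly zero
  lineage <- make_lineage(domain = "Bacteria", genus = rows$genus)
  tab <- stratified_table(ec_r, lineage, vals, metadata)
  shares <- design$gene_weights / sum(design$gene_weights)
  truth <- list(expected = mu, gene = gene_r, genus = rows$genus,
                gene_shares = shares,
                dominant_genus = vapply(design$genus_boost,
                                        function(b) names(b)[which.max(b)],
                                        character(1)),
                treatment_totals = design$treatment_totals)
  list(table = tab, metadata = metadata, truth = truth)
}

#' Generate synthetic per-sample soil properties
#'
#' Each property has a planted per-treatment mean; replicate values are the
#' mean times `(1 + N(0, noise_sigma))` (fractional noise), so zero noise
#' reproduces the planted means exactly. A stand-in for measured soil
#' physicochemistry feeding the correlation screen; it makes no attempt to
#' model real soil covariance structure.
#'
#' @param metadata a [sample_metadata()] table.
#' @param effect_map named list `property -> named numeric (treatment ->
#'   mean)`; see [default_soil_effects()].
#' @param noise_sigma fractional noise sd (>= 0).
#' @param seed integer seed.
#' @return a [soil_properties()] table.
#' @export
generate_soil_properties <- function(metadata, effect_map, noise_sigma,
                                     seed) {
  stopifnot(inherits(metadata, "sample_metadata"), noise_sigma >= 0)
  trts <- unique(metadata$treatment)
  for (p in names(effect_map)) {
    if (!all(trts %in% names(effect_map[[p]]))) {
      stop("effect_map for '", p, "' does not cover every treatment")
    }
  }
  old <- .local_seed(.stage_seed(seed, "soil"))
  on.exit(.restore_seed(old))
  cols <- lapply(effect_map, function(means) {
    mu <- as.numeric(means[metadata$treatment])
    mu * (1 + rnorm(nrow(metadata), 0, noise_sigma))
  })
  do.call(soil_properties, c(list(sample_id = metadata$sample_id), cols))
}

#' Reference soil-property effect map
#'
#' Planted per-treatment means for the standard property set (electrical
#' conductivity, pH, total organic carbon, total nitrogen, available
#' phosphorus, water-holding capacities at -1500 and -33 kPa, basal
#' respiration, urease and phosphatase activities, total bacterial fatty
#' acids), following the qualitative pattern of amended vs unamended soils:
#' sludge-containing treatments highest in EC, nutrients and microbial
#' activity; unamended soils highest in pH.
#'
#' @return named list usable as `effect_map` in
#'   [generate_soil_properties()].
#' @export
default_soil_effects <- function() {
  t7 <- c("Natural", "Control", "COVG", "COHort", "SS", "COVG+SS",
          "COHort+SS")
  m <- function(...) setNames(c(...), t7)
  list(
    EC = m(0.2, 0.25, 0.9, 1.1, 2.0, 1.6, 1.7),
    pH = m(8.4, 8.5, 8.0, 7.9, 7.4, 7.6, 7.6),
    TOC = m(1.1, 0.4, 2.1, 2.9, 2.6, 1.9, 2.8),
    TN = m(0.12, 0.05, 0.18, 0.22, 0.30, 0.26, 0.28),
    AP = m(8, 8, 25, 35, 60, 45, 50),
    pF1500 = m(9, 8, 12, 13, 14, 13, 14),
    pF33 = m(18, 17, 20, 21, 22, 21, 22),
    basal_respiration = m(1.1, 0.8, 1.2, 2.0, 2.6, 2.4, 2.5),
    urease = m(1.6, 1.0, 1.2, 1.2, 1.0, 1.1, 1.1),
    phosphatase = m(0.6, 0.5, 0.9, 1.0, 1.8, 1.4, 1.5),
    TB_FA = m(55, 30, 60, 45, 85, 80, 80))
}
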