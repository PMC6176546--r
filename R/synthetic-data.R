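# Synthetic multi-species DIA data with known ground truth.
#
# The generator emulates the statistical structure of a targeted-extraction
# peptide report: log-normal protein abundances spanning several orders of
# magnitude, peptide-specific response factors, multiplicative observation
# noise, a small fraction of low-confidence observations biased to low
# intensities, and tryptic peptides that are either sequence-identical in all
# species (conserved) or carry substitutions in some species.

AA_INTERNAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
                 "N", "Q", "S", "T", "V", "W", "Y")  # 20 aa minus K, R, P

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic data generator. Defaults
#' mirror a four-species (two rodents, two primates) hippocampal synaptosome
#' comparison with 5/5/6/5 biological replicates.
#'
#' @param seed master seed; every generator stage derives its own stream.
#' @param species named integer vector: samples per species.
#' @param groups named character vector: species -> comparison group.
#' @param n_genes number of genes (one protein per species each).
#' @param peptides_per_gene integer range, peptides drawn uniformly.
#' @param conserved_fraction probability a peptide is sequence-identical in
#'   all species.
#' @param de_fraction fraction of genes with a true group effect.
#' @param log2fc_range magnitude range of true log2 fold changes (sign
#'   random).
#' @param response_factor_sd sd of peptide log10 response factors.
#' @param species_effect_sd sd (log2 scale) of per-gene per-species abundance
#'   offsets, emulating species-level biological divergence beyond the group
#'   contrast. Default 0: the group effect is then the only systematic
#'   difference, which keeps the two-group null exact for FDR studies; set
#'   it above the noise level to make samples cluster by species.
#' @param noise_cv multiplicative per-observation coefficient of variation.
#' @param lowconf_fraction fraction of observations assigned a low-confidence
#'   Q-value (placed preferentially on low intensities).
#' @param lowconf_q_range,highconf_q_range uniform Q-value ranges for
#'   low/high confidence observations.
#' @param abundance_log10_mean,abundance_log10_sd log10-normal parameters of
#'   gene base abundance (sd 0.8 spans roughly 6 orders of magnitude over
#'   thousands of genes).
#' @param reference_species species whose peptide sequences the report
#'   carries (the spectral-library species).
#' @param contrast ordered pair of group labels (A vs B).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       species = c(mouse = 5L, rat = 5L, marmoset = 6L, human = 5L),
                       groups = c(mouse = "rodent", rat = "rodent",
                                  marmoset = "primate", human = "primate"),
                       n_genes = 2000L,
                       peptides_per_gene = c(2L, 8L),
                       conserved_fraction = 0.7,
                       de_fraction = 0.1,
                       log2fc_range = c(0.2, 2.0),
                       response_factor_sd = 1.0,
                       species_effect_sd = 0,
                       noise_cv = 0.10,
                       lowconf_fraction = 0.02,
                       lowconf_q_range = c(2e-4, 1e-2),
                       highconf_q_range = c(0, 1e-5),
                       abundance_log10_mean = 5,
                       abundance_log10_sd = 0.8,
                       reference_species = "human",
                       contrast = c("rodent", "primate")) {
  stop_if_not(length(species) >= 2 && all(species >= 2),
              "need >= 2 species with >= 2 samples each")
  stop_if_not(!is.null(names(species)) && !anyDuplicated(names(species)),
              "species must be uniquely named")
  stop_if_not(all(names(species) %in% names(groups)),
              "every species needs a group assignment")
  stop_if_not(n_genes >= 1, "n_genes must be positive")
  stop_if_not(length(peptides_per_gene) == 2 && all(peptides_per_gene >= 1) &&
                peptides_per_gene[1] <= peptides_per_gene[2],
              "peptides_per_gene must be a positive non-decreasing pair")
  for (p in c(conserved_fraction, de_fraction, lowconf_fraction)) {
    stop_if_not(p >= 0 && p <= 1, "fractions must lie in [0, 1]")
  }
  stop_if_not(noise_cv >= 0, "noise_cv must be >= 0")
  stop_if_not(response_factor_sd >= 0, "response_factor_sd must be >= 0")
  stop_if_not(species_effect_sd >= 0, "species_effect_sd must be >= 0")
  stop_if_not(reference_species %in% names(species),
              "reference_species must be one of the simulated species")
  stop_if_not(all(contrast %in% groups), "contrast groups not in group map")
  structure(list(
    seed = as.integer(seed), species = species, groups = groups[names(species)],
    n_genes = as.integer(n_genes),
    peptides_per_gene = as.integer(peptides_per_gene),
    conserved_fraction = conserved_fraction, de_fraction = de_fraction,
    log2fc_range = log2fc_range, response_factor_sd = response_factor_sd,
    species_effect_sd = species_effect_sd,
    noise_cv = noise_cv, lowconf_fraction = lowconf_fraction,
    lowconf_q_range = lowconf_q_range, highconf_q_range = highconf_q_range,
    abundance_log10_mean = abundance_log10_mean,
    abundance_log10_sd = abundance_log10_sd,
    reference_species = reference_species, contrast = contrast
  ), class = "sim_config")
}

random_tryptic_block <- function(len) {
  paste0(paste(sample(AA_INTERNAL, len - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

substitute_internal <- function(block) {
  chars <- strsplit(block, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(chars) - 1L, 1L)  # never the terminal K/R
  chars[pos] <- sample(setdiff(AA_INTERNAL, chars[pos]), 1L)
  paste(chars, collapse = "")
}

#' Generate per-species proteomes with controlled peptide conservation
#'
#' Each gene yields one protein per species, built as a concatenation of
#' tryptic blocks (length 6--20, ending in K/R, no internal K/R/P). A block
#' is either identical in all species or carries at least one substitution in
#' at least one species; substitutions never touch K/R/P, so tryptic
#' boundaries are aligned across species.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_proteomes`: list with `proteomes` (named list
#'   of `proteome` objects), `peptides` (ground-truth peptide annotation:
#'   peptide_id, gene, conserved, sequence in the reference species),
#'   `sequences` (peptide x species matrix of block sequences) and `config`.
#' @export
simulate_proteomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  sp <- names(config$species)
  n_sp <- length(sp)
  n_pep_gene <- sample(seq(config$peptides_per_gene[1L], config$peptides_per_gene[2L]),
                       config$n_genes, replace = TRUE)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  parent <- rep(genes, n_pep_gene)
  n_pep <- length(parent)
  lens <- sample(6:20, n_pep, replace = TRUE)
  base_blocks <- vapply(lens, random_tryptic_block, "")
  # peptide sequences are unique across the simulated library, as precursor
  # keys in a spectral library are; short blocks can otherwise collide
  repeat {
    dup <- which(duplicated(base_blocks))
    if (!length(dup)) break
    base_blocks[dup] <- vapply(lens[dup], random_tryptic_block, "")
  }
  conserved <- stats::runif(n_pep) < config$conserved_fraction
  seq_mat <- matrix(base_blocks, nrow = n_pep, ncol = n_sp,
                    dimnames = list(NULL, sp))
  pool <- new.env(hash = TRUE, parent = emptyenv())
  for (b in base_blocks) assign(b, TRUE, envir = pool)
  for (i in which(!conserved)) {
    k_div <- sample.int(n_sp - 1L, 1L)
    for (s in sample(sp, k_div)) {
      repeat {
        cand <- substitute_internal(base_blocks[i])
        if (is.null(pool[[cand]])) break
      }
      assign(cand, TRUE, envir = pool)
      seq_mat[i, s] <- cand
    }
  }
  pep_ids <- sprintf("pep%06d", seq_len(n_pep))
  rownames(seq_mat) <- pep_ids
  proteomes <- lapply(sp, function(s) {
    seqs <- vapply(split(seq_mat[, s], parent), paste, "", collapse = "")
    seqs <- seqs[genes]  # original gene order
    structure(list(
      species = s,
      entries = data.frame(
        accession = paste0(genes, "_", toupper(s)),
        gene = genes, sequence = unname(seqs), stringsAsFactors = FALSE)
    ), class = "proteome")
  })
  names(proteomes) <- sp
  peptides <- data.frame(
    peptide_id = pep_ids, gene = parent, conserved = conserved,
    sequence = seq_mat[, config$reference_species],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(proteomes = proteomes, peptides = peptides,
                 sequences = seq_mat, config = config),
            class = "sim_proteomes")
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))  # mean-1 multiplier
}

sample_table <- function(species_counts, groups, suffix = "") {
  sp <- rep(names(species_counts), species_counts)
  idx <- unlist(lapply(species_counts, seq_len), use.names = FALSE)
  data.frame(
    sample_id = paste0(sp, suffix, "_", idx),
    species = sp, group = unname(groups[sp]),
    stringsAsFactors = FALSE
  )
}

assign_qvalues <- function(intensity, config) {
  n <- length(intensity)
  q <- stats::runif(n, config$highconf_q_range[1L], config$highconf_q_range[2L])
  n_low <- round(config$lowconf_fraction * n)
  if (n_low > 0) {
    low_idx <- sample.int(n, n_low, prob = 1 / intensity)
    q[low_idx] <- stats::runif(n_low, config$lowconf_q_range[1L],
                               config$lowconf_q_range[2L])
  }
  q
}

#' Generate a peptide-level quantification report with ground truth
#'
#' Intensity of an observation is (species-level gene abundance) x (peptide
#' response factor) x (log-normal noise with the configured CV, mean 1).
#' Every (sample, precursor) pair appears exactly once (targeted extraction
#' yields complete matrices). Q-values mark a configured fraction of
#' observations as low-confidence, preferentially at low intensities.
#'
#' @param config a [sim_config()].
#' @param prot result of [simulate_proteomes()] for the same config.
#' @return list with `report` (QuantReport data.frame), `design` (sample
#'   table) and `truth` (ground truth: `genes`, `peptides`, `observations`).
#' @export
simulate_report <- function(config, prot = simulate_proteomes(config)) {
  stopifnot(inherits(prot, "sim_proteomes"))
  sp <- names(config$species)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))

  set.seed(derive_seed(config$seed, 2L))
  base <- 10^stats::rnorm(config$n_genes, config$abundance_log10_mean,
                          config$abundance_log10_sd)
  n_de <- round(config$de_fraction * config$n_genes)
  de_idx <- if (n_de > 0) sample.int(config$n_genes, n_de) else integer(0)
  fc <- numeric(config$n_genes)
  if (n_de > 0) {
    fc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, config$log2fc_range[1L], config$log2fc_range[2L])
  }
  # species means: half the fold change up in group A, half down in group B
  group_mult <- vapply(sp, function(s) {
    g <- config$groups[[s]]
    if (g == config$contrast[1L]) 2^(fc / 2)
    else if (g == config$contrast[2L]) 2^(-fc / 2)
    else rep(1, config$n_genes)
  }, numeric(config$n_genes))
  species_mean <- base * group_mult  # genes x species
  if (config$species_effect_sd > 0) {
    species_mean <- species_mean *
      2^matrix(stats::rnorm(length(species_mean), 0, config$species_effect_sd),
               nrow = config$n_genes)
  }
  dimnames(species_mean) <- list(genes, sp)

  set.seed(derive_seed(config$seed, 3L))
  n_pep <- nrow(prot$peptides)
  rf <- 10^stats::rnorm(n_pep, 0, config$response_factor_sd)

  design <- sample_table(config$species, config$groups)
  n_samples <- nrow(design)
  pep_idx <- rep(seq_len(n_pep), times = n_samples)
  smp_idx <- rep(seq_len(n_samples), each = n_pep)
  expected <- species_mean[cbind(match(prot$peptides$gene[pep_idx], genes),
                                 match(design$species[smp_idx], sp))] * rf[pep_idx]

  set.seed(derive_seed(config$seed, 4L))
  noise <- lognormal_noise(length(expected), config$noise_cv)
  intensity <- expected * noise

  set.seed(derive_seed(config$seed, 5L))
  q <- assign_qvalues(intensity, config)

  report <- data.frame(
    sample_id = design$sample_id[smp_idx],
    species = design$species[smp_idx],
    sequence = prot$peptides$sequence[pep_idx],
    modifications = "", charge = 2L,
    genes = prot$peptides$gene[pep_idx],
    intensity = intensity, q_value = q,
    stringsAsFactors = FALSE
  )
  truth <- list(
    genes = data.frame(
      gene = genes, base_abundance = base, true_log2fc = fc,
      de_flag = fc != 0, stringsAsFactors = FALSE),
    species_means = species_mean,
    peptides = cbind(prot$peptides, response_factor = rf),
    observations = data.frame(
      sample_id = design$sample_id[smp_idx],
      peptide_id = prot$peptides$peptide_id[pep_idx],
      noise = noise, stringsAsFactors = FALSE)
  )
  list(report = report, design = design, truth = truth)
}

#' Generate technical replicates of a single preparation
#'
#' Replicates share the same true abundances (one species, no group effect);
#' only the observation noise differs between replicate runs.
#'
#' @param config a [sim_config()]; `noise_cv` sets the technical variation.
#' @param n_reps number of replicate runs (>= 2).
#' @param species species of the preparation.
#' @param prot result of [simulate_proteomes()] for the same config.
#' @return list with `report`, `design` and `truth` as in
#'   [simulate_report()].
#' @export
simulate_technical_replicates <- function(config, n_reps = 3L, species = "mouse",
                                          prot = simulate_proteomes(config)) {
  stop_if_not(n_reps >= 2, "n_reps must be >= 2")
  stop_if_not(species %in% names(config$species), "unknown species '%s'", species)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  set.seed(derive_seed(config$seed, 2L))
  base <- 10^stats::rnorm(config$n_genes, config$abundance_log10_mean,
                          config$abundance_log10_sd)
  set.seed(derive_seed(config$seed, 3L))
  n_pep <- nrow(prot$peptides)
  rf <- 10^stats::rnorm(n_pep, 0, config$response_factor_sd)

  design <- data.frame(
    sample_id = paste0(species, "_rep_", seq_len(n_reps)),
    species = species, group = "technical", stringsAsFactors = FALSE)
  pep_idx <- rep(seq_len(n_pep), times = n_reps)
  smp_idx <- rep(seq_len(n_reps), each = n_pep)
  expected <- base[match(prot$peptides$gene[pep_idx], genes)] * rf[pep_idx]
  set.seed(derive_seed(config$seed, 6L))
  noise <- lognormal_noise(length(expected), config$noise_cv)
  intensity <- expected * noise
  set.seed(derive_seed(config$seed, 7L))
  q <- assign_qvalues(intensity, config)
  report <- data.frame(
    sample_id = design$sample_id[smp_idx], species = species,
    sequence = prot$peptides$sequence[pep_idx],
    modifications = "", charge = 2L,
    genes = prot$peptides$gene[pep_idx],
    intensity = intensity, q_value = q, stringsAsFactors = FALSE)
  truth <- list(
    genes = data.frame(gene = genes, base_abundance = base,
                       stringsAsFactors = FALSE),
    peptides = cbind(prot$peptides, response_factor = rf),
    observations = data.frame(
      sample_id = design$sample_id[smp_idx],
      peptide_id = prot$peptides$peptide_id[pep_idx],
      noise = noise, stringsAsFactors = FALSE))
  list(report = report, design = design, truth = truth)
}

#' Generate a full synthetic dataset (proteomes + report + design + truth)
#'
#' @param config a [sim_config()].
#' @return list with `proteomes` (named list), `report`, `design`, `truth`
#'   and the peptide annotation under `truth$peptides`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  prot <- simulate_proteomes(config)
  rep_ <- simulate_report(config, prot)
  list(proteomes = prot$proteomes, report = rep_$report,
       design = rep_$design, truth = rep_$truth, config = config)
}
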