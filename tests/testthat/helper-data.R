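# Shared fixtures built in code.

# Small but structurally complete simulation config for fast tests.
small_config <- function(seed = 1L, n_genes = 150L, ...) {
  sim_config(
    seed = seed,
    species = c(mouse = 3L, rat = 2L, marmoset = 2L, human = 2L),
    n_genes = n_genes,
    peptides_per_gene = c(2L, 4L),
    ...
  )
}

# Hand-built long-format report: q is a precursors x samples matrix of
# Q-values; intensity defaults to 1000 everywhere.
make_report <- function(q, samples, species, genes = NULL, intensity = NULL) {
  n_prec <- nrow(q); n_smp <- ncol(q)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(n_prec))
  seqs <- vapply(seq_len(n_prec),
                 function(i) paste0(strrep("A", 5 + i), "K"), "")
  if (is.null(intensity)) intensity <- matrix(1000, n_prec, n_smp)
  data.frame(
    sample_id = rep(samples, each = n_prec),
    species = rep(species, each = n_prec),
    sequence = rep(seqs, n_smp),
    modifications = "", charge = 2L,
    genes = rep(genes, n_smp),
    intensity = as.vector(intensity),
    q_value = as.vector(q),
    stringsAsFactors = FALSE
  )
}

make_design <- function(samples, species, groups) {
  data.frame(sample_id = samples, species = species, group = groups,
             stringsAsFactors = FALSE)
}
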