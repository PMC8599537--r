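# Small in-code fixtures shared across test files.

# quick single-species simulation, sized for speed
tiny_sim <- function(n_cpgs = 200, n = 20, n_age = 10, seed = 1, ...) {
  simulate_methylation(sim_config(n_cpgs = n_cpgs, n_per_species = n,
                                  n_age_cpgs = n_age, seed = seed, ...))
}

# two-species marmoset + human-like configuration
two_species_config <- function(seed, n_marmoset = 60, n_human = 40,
                               n_cpgs = 2000, ...) {
  sim_config(
    n_cpgs = n_cpgs, n_per_species = c(n_marmoset, n_human),
    species = list(
      marmoset = list(max_lifespan = 22.8, age_range = c(0.5, 15.5)),
      human = list(max_lifespan = 122.5, age_range = c(0, 93))),
    seed = seed, ...)
}

# beta matrix with a prescribed number of pure-noise CpGs
noise_betas <- function(n_cpgs, n, seed = 1) {
  set.seed(seed)
  matrix(runif(n_cpgs * n, 0.1, 0.9), n_cpgs, n,
         dimnames = list(sprintf("cg%06d", seq_len(n_cpgs)),
                         sprintf("s%03d", seq_len(n))))
}

# toy probe annotation over the given ids
toy_annotation <- function(cpg_ids, classes) {
  data.frame(cpg_id = cpg_ids,
             chrom = "chr1",
             pos = seq_along(cpg_ids) * 100L,
             gene = paste0("GENE", seq_along(cpg_ids)),
             tss_distance = seq_along(cpg_ids) * 10L - 500L,
             region_class = classes,
             stringsAsFactors = FALSE)
}
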