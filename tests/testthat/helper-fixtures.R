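# shared fixtures, built in code

# small but fully structured simulation: fast enough for per-test generation
small_sim_config <- function(seed, ...) {
  args <- list(seed = seed, n_genes = 150L, n_families = 60L,
               exclusive_counts = c(F = 2L, N = 1L, P = 1L, X = 10L),
               n_ballast = 5L, n_ambiguous = 20L, n_homopolymer = 10L,
               n_background = 200L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# hand-built count table
toy_counts <- function() {
  data.frame(signature = c("GATCAAAAACCCCCTTTTTGG",
                           "GATCTTTTTGGGGGAAAAACC",
                           "GATCGGGGGTTTTTCCCCCAA"),
             F = c(2L, 3L, 5L), X = c(0L, 5L, 5L))
}

qc_pipeline <- function(counts, config = qc_config()) {
  filter_min_abundance(
    normalize_tpm(filter_homopolymer(filter_deterministic(counts), config),
                  config),
    config)
}
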