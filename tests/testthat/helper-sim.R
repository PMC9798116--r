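# Shared simulation shortcuts for the suite.

# Normalise, QC-filter and quantify a simulated experiment in one step.
quick_quant <- function(sim, ...) {
  sim$intensity |>
    normalize_spikein() |>
    qc_filter() |>
    compute_quant_table(sim$samples, ...)
}

# A single planted gene simulated under the given noise level.
single_gene_sim <- function(category, effect_size = 4, noise_sigma = 0,
                            seed = 1) {
  pl <- planted_genes(category, effect_size)
  cfg <- sim_config(
    n_genes = 1, planted = pl, noise_sigma = noise_sigma,
    n_spikeins = 5, flag_absent_rate = 0, flag_low_quantile = 0,
    seed = seed
  )
  list(sim = simulate_experiment(cfg), gene = pl$gene_symbol)
}
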