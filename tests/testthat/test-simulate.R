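test_that("noise-free simulation is the deterministic measurement model", {
  pl <- planted_genes("null", 4)
  pl$m_OA <- pl$m_HP <- pl$m_SOMA <- 0.4
  pl$t_OA <- pl$t_HP <- pl$t_SOMA <- 100
  cfg <- sim_config(
    n_genes = 1, planted = pl, noise_sigma = 0, n_spikeins = 2,
    flag_absent_rate = 0, flag_low_quantile = 0, seed = 1
  )
  sim <- simulate_experiment(cfg)
  for (s in sim$samples$sample_id) {
    expect_equal(sim$intensity[[paste0("IP_", s)]][1], 40)
    expect_equal(sim$intensity[[paste0("Sup_", s)]][1], 60)
  }
  # spike-ins constant at the configured level in both channels
  spk <- sim$intensity[sim$intensity$is_spikein, ]
  expect_true(all(spk$IP_OA1 == cfg$spikein_level))
  expect_true(all(spk$Sup_SOMA3 == cfg$spikein_level))
})

test_that("the seed contract holds: same seed identical, different seed different", {
  cfg42 <- sim_config(n_genes = 30, seed = 42)
  a <- simulate_experiment(cfg42)
  b <- simulate_experiment(cfg42)
  expect_identical(a, b)
  c <- simulate_experiment(sim_config(n_genes = 30, seed = 43))
  expect_false(identical(a$intensity, c$intensity))
  expect_identical(a$samples, c$samples) # design is seed-independent
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  pl <- planted_genes("v", 4)
  pl$m_SOMA <- 1.2
  expect_error(sim_config(n_genes = 1, planted = pl), "planted")
  pl2 <- planted_genes("v", 4)
  pl2$t_HP <- -5
  expect_error(sim_config(n_genes = 1, planted = pl2), "planted")
  expect_error(sim_config(noise_sigma = -1), "noise_sigma")
})

test_that("planted profiles realise their categories and the null is flat", {
  prof_null <- planted_profile("null")
  expect_equal(length(unique(prof_null$m)), 1)
  expect_equal(length(unique(prof_null$t)), 1)
  expect_error(planted_profile("vi"), "category")
  expect_error(planted_profile("v", effect_size = 1), "effect_size")

  # round trip: noise-free features of every planted profile classify back
  # to the planted category
  for (cat_ in c("i", "ii", "iii", "iv", "v")) {
    sg <- single_gene_sim(cat_, effect_size = 4, noise_sigma = 0)
    quant <- quick_quant(sg$sim)
    call <- classify_evidence(extract_features(quant, sg$sim$samples))
    expect_equal(
      as.character(call$category[call$gene_symbol == sg$gene]), cat_,
      label = paste("planted category", cat_)
    )
  }
})

test_that("category-iii profile gives discordant expression directions", {
  prof <- planted_profile("iii", 4)
  t_oa <- prof$t[prof$group == "OA"]
  expect_gt(prof$t[prof$group == "HP"], t_oa)
  expect_lt(prof$t[prof$group == "SOMA"], t_oa)
})

test_that("total intensity tracks true abundance and level converges to the truth", {
  pl <- planted_genes("null", 4)
  cfg <- sim_config(
    n_genes = 1, planted = pl, noise_sigma = 0.05, n_spikeins = 2,
    flag_absent_rate = 0, flag_low_quantile = 0, seed = 9
  )
  sim <- simulate_experiment(cfg)
  tot <- sim$intensity$IP_OA1[1] + sim$intensity$Sup_OA1[1]
  expect_equal(tot / pl$t_OA, 1, tolerance = 0.2) # noisy multiple of T
  # mean level over many replicates approaches 100 m as sigma shrinks
  cfg_lo <- sim_config(
    n_genes = 1, planted = pl, noise_sigma = 0.01, n_per_group = 50,
    n_spikeins = 2, flag_absent_rate = 0, flag_low_quantile = 0, seed = 10
  )
  q <- compute_quant_table(simulate_experiment(cfg_lo)$intensity,
                           aggregate = "median")
  expect_equal(mean(q$level), 100 * pl$m_OA, tolerance = 0.5)
})
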