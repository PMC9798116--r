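test_that("spike-in normalisation drives every sample/channel median to target", {
  sim <- simulate_experiment(sim_config(n_genes = 40, n_spikeins = 7,
                                        noise_sigma = 0.3, seed = 6))
  norm <- normalize_spikein(sim$intensity, target = 500)
  long <- norm[norm$is_spikein, ]
  for (s in sim$samples$sample_id) {
    expect_equal(median(long[[paste0("IP_", s)]]), 500)
    expect_equal(median(long[[paste0("Sup_", s)]]), 500)
  }
})

test_that("normalisation is the identity when medians already sit at target", {
  sim <- simulate_experiment(sim_config(n_genes = 10, n_spikeins = 3,
                                        noise_sigma = 0, spikein_level = 800,
                                        seed = 1))
  norm <- normalize_spikein(sim$intensity, target = 800)
  expect_equal(as.data.frame(norm), as.data.frame(sim$intensity),
               ignore_attr = TRUE)
})

test_that("normalisation removes a per-channel scale distortion", {
  sim <- simulate_experiment(sim_config(n_genes = 25, n_spikeins = 5,
                                        noise_sigma = 0.2, seed = 8))
  scaled <- sim$intensity
  scaled$IP_HP1 <- scaled$IP_HP1 * 10
  a <- normalize_spikein(sim$intensity, target = 1000)
  b <- normalize_spikein(scaled, target = 1000)
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("normalisation fails without usable spike-ins", {
  sim <- simulate_experiment(sim_config(n_genes = 5, n_spikeins = 0, seed = 1))
  expect_error(normalize_spikein(sim$intensity), "no spike-in")
})

test_that("the QC retention rule keeps >= min_pm P/M flags, on the 3-of-9 boundary", {
  sim <- simulate_experiment(sim_config(n_genes = 3, n_spikeins = 1, seed = 2))
  tbl <- sim$intensity
  flags <- paste0("flag_", sim$samples$sample_id)
  set_flags <- function(tbl, row, pattern) {
    for (j in seq_along(flags)) tbl[[flags[j]]][row] <- pattern[j]
    tbl
  }
  tbl <- set_flags(tbl, 1, c("P", "P", "P", rep("A", 6))) # exactly 3 -> keep
  tbl <- set_flags(tbl, 2, c("P", "M", rep("A", 7))) # 2 of 9 -> drop
  tbl <- set_flags(tbl, 3, rep("M", 9)) # M counts as pass
  kept <- qc_filter(tbl, min_pm = 3)
  expect_true(tbl$probe_id[1] %in% kept$probe_id)
  expect_false(tbl$probe_id[2] %in% kept$probe_id)
  expect_true(tbl$probe_id[3] %in% kept$probe_id)
  # spike-ins ride along regardless of flags
  expect_true(all(tbl$probe_id[tbl$is_spikein] %in% kept$probe_id))
  expect_error(qc_filter(tbl, min_pm = 10), "min_pm")
})

test_that("qc_filter is monotone under flag upgrades and commutes with normalisation", {
  sim <- simulate_experiment(sim_config(n_genes = 60, n_spikeins = 4,
                                        flag_absent_rate = 0.4, seed = 13))
  tbl <- sim$intensity
  kept_before <- qc_filter(tbl)$probe_id
  upgraded <- tbl
  upgraded$flag_OA1 <- "P"
  kept_after <- qc_filter(upgraded)$probe_id
  expect_true(all(kept_before %in% kept_after))
  expect_lte(nrow(qc_filter(tbl)), nrow(tbl))

  a <- qc_filter(normalize_spikein(tbl, target = 900))
  b <- normalize_spikein(qc_filter(tbl), target = 900)
  expect_equal(as.data.frame(a), as.data.frame(b))
})
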