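test_that("group_test matches independent oracles", {
  a <- c(5.1, 5.3, 4.9)
  b <- c(3.0, 3.2, 2.8)
  expect_equal(group_test(a, b, "t_welch"), welch_p_oracle(a, b))
  expect_equal(group_test(c(1, 2, 3), c(10, 11, 12), "mannwhitney"), 0.1)
  expect_equal(
    group_test(c(1, 2, 3), c(10, 11, 12), "mannwhitney"),
    mw_exact_p_oracle(c(1, 2, 3), c(10, 11, 12))
  )
  set.seed(31)
  for (i in 1:10) {
    x <- round(rnorm(4, 0, 3), 3)
    y <- round(rnorm(3, 1, 3), 3)
    expect_equal(group_test(x, y, "t_welch"), welch_p_oracle(x, y))
    expect_equal(group_test(x, y, "mannwhitney"), mw_exact_p_oracle(x, y))
  }
})

test_that("degenerate group_test inputs follow the documented rules", {
  expect_equal(group_test(c(2, 2, 2), c(2, 2, 2), "t_welch"), 1)
  expect_equal(group_test(c(2, 2, 2), c(2, 2, 2), "mannwhitney"), 1)
  expect_equal(group_test(c(8, 8, 8), c(2, 2, 2), "t_welch"), 0)
  expect_error(group_test(1, c(1, 2)), "at least 2")
  expect_error(group_test(c(1, NA, 2), c(1, 2)), "finite")
})

test_that("compare_groups computes geometric-mean fold changes and flags", {
  sim <- simulate_experiment(sim_config(n_genes = 2, n_spikeins = 1,
                                        noise_sigma = 0, seed = 1))
  quant <- quick_quant(sim)
  cmp <- compare_groups(quant, sim$samples, "expression", "SOMA/OA")
  expect_equal(cmp$log2fc, rep(0, nrow(cmp)))
  expect_false(any(cmp$significant))
  expect_equal(cmp$p, rep(1, nrow(cmp)))

  # planted 4-fold difference: groups {8,8,8} vs {2,2,2}
  q <- tibble::tibble(
    gene_symbol = "G",
    sample_id = sim$samples$sample_id,
    level = 50,
    quantity = ifelse(sim$samples$group == "SOMA", 8, 2),
    expression = ifelse(sim$samples$group == "SOMA", 8, 2)
  )
  cmp2 <- compare_groups(q, sim$samples, "quantity", "SOMA/OA")
  expect_equal(cmp2$fc, 4)
  expect_equal(cmp2$direction, "up")
  expect_equal(cmp2$magnitude, "double")
})

test_that("contrast antisymmetry: reversing inverts fc and keeps p", {
  sim <- simulate_experiment(sim_config(n_genes = 30, noise_sigma = 0.3, seed = 17))
  quant <- quick_quant(sim)
  fwd <- compare_groups(quant, sim$samples, "expression", "SOMA/OA")
  rev <- compare_groups(quant, sim$samples, "expression", "OA/SOMA")
  expect_equal(fwd$fc, 1 / rev$fc)
  expect_equal(fwd$p, rev$p)
  flip <- c(up = "down", down = "up")
  expect_equal(fwd$direction, unname(flip[rev$direction]))
  expect_equal(fwd$significant, rev$significant)
})

test_that("level contrasts skip the fold-change cutoff; intensity screens apply it", {
  sheet <- tibble::tibble(
    sample_id = paste0(rep(c("OA", "HP", "SOMA"), each = 3), 1:3),
    group = factor(rep(c("OA", "HP", "SOMA"), each = 3),
                   levels = c("OA", "HP", "SOMA")),
    replicate = rep(1:3, 3)
  )
  # strong significance but only a 1.5-fold change
  vals <- ifelse(sheet$group == "SOMA", 30, 20) + rep(c(-0.01, 0, 0.01), 3)
  q <- tibble::tibble(
    gene_symbol = "G", sample_id = sheet$sample_id,
    level = vals, quantity = vals, expression = vals
  )
  lvl <- compare_groups(q, sheet, "level", "SOMA/OA")
  qty <- compare_groups(q, sheet, "quantity", "SOMA/OA")
  expect_lt(lvl$p, 0.05)
  expect_true(lvl$significant)
  expect_false(qty$significant) # fc ~1.5 under the 2-fold cutoff
})

test_that("arrow coding is total and matches the notation rules", {
  expect_equal(arrow_code("up", 1.5, FALSE), "↑")
  expect_equal(arrow_code("down", 4, TRUE), "↓↓*")
  expect_equal(arrow_code("up", 2, TRUE), "↑↑*") # boundary inclusive
  expect_equal(arrow_code("down", 1 / 1.2, FALSE), "↓")
  grid <- expand.grid(
    direction = c("up", "down"), fc = c(1.01, 1.99, 2, 8),
    significant = c(TRUE, FALSE), stringsAsFactors = FALSE
  )
  codes <- arrow_code(grid$direction, grid$fc, grid$significant)
  expect_false(any(is.na(codes)))
  back <- parse_arrow(codes)
  expect_equal(back$direction, grid$direction)
  expect_equal(back$significant, grid$significant)
  expect_error(parse_arrow("<>"), "unparseable")
})

test_that("tendency classifies ordered trajectories with non-strict interior", {
  expect_equal(tendency(10, 7, 3), "decreasing")
  expect_equal(tendency(10, 12, 3), "unordered")
  expect_equal(tendency(10, 10, 4), "decreasing")
  expect_equal(tendency(3, 7, 10), "increasing")
  expect_equal(tendency(4, 4, 4), "unordered")
  expect_error(tendency(1, NA, 3), "finite")
})

test_that("the null screen is calibrated on simulated null genes", {
  # invariant check at n = 6 per group, where the Welch test holds its size
  cfg <- sim_config(n_genes = 2000, null_fraction = 1, n_per_group = 6,
                    noise_sigma = 0.2, seed = 5)
  sim <- simulate_experiment(cfg)
  quant <- compute_quant_table(sim$intensity, sim$samples)
  cmp <- compare_groups(quant, sim$samples, "expression", "SOMA/OA")
  frac <- mean(cmp$p < 0.05, na.rm = TRUE)
  band <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), band)
})
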