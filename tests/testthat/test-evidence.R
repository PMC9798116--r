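test_that("the packaged candidate fixture parses to 14 feature rows", {
  fx <- load_candidate_fixture()
  expect_equal(nrow(fx), 14)
  expect_equal(sum(grepl("v", fx$evidence_printed) &
                     grepl("Yes", fx$evidence_printed) &
                     !grepl("iv", fx$evidence_printed)), 4)
  expect_equal(fx$quantity_sig[fx$gene_symbol == "BDNF"], TRUE)
  expect_equal(fx$expr_hp_mag[fx$gene_symbol == "MITF"], "double")
  expect_equal(fx$expr_hp_sig[fx$gene_symbol == "MITF"], TRUE)
  expect_equal(fx$expr_soma_mag[fx$gene_symbol == "CTXN2"], "double")
  expect_equal(fx$expr_soma_sig[fx$gene_symbol == "CTXN2"], FALSE)
})

test_that("the classifier reproduces the printed verdict for all 14 candidates", {
  fx <- load_candidate_fixture()
  ev <- classify_evidence(fx)
  printed_cat <- sub(".*\\((.*)\\)", "\\1", fx$evidence_printed)
  printed_mech <- ifelse(grepl("^Yes", fx$evidence_printed), "Yes", "No")
  expect_equal(as.character(ev$category), printed_cat)
  expect_equal(ev$mechanism, printed_mech)
  counts <- table(ev$category)
  expect_equal(as.integer(counts), c(2L, 1L, 5L, 2L, 4L))
  # the four strongest candidates
  expect_setequal(
    ev$gene_symbol[ev$category == "v"],
    c("BDNF", "TMEM38B", "RPL3L", "C22orf42")
  )
})

test_that("named worked examples land in their categories", {
  fx <- load_candidate_fixture()
  ev <- classify_evidence(fx)
  cat_of <- function(g) as.character(ev$category[ev$gene_symbol == g])
  expect_equal(cat_of("MITF"), "i")
  expect_equal(cat_of("NPPB"), "ii")
  expect_equal(cat_of("CLEC7A"), "iii")
  expect_equal(cat_of("CCDC61"), "iii") # significant arrow yet still iii
  expect_equal(cat_of("CTXN2"), "iv")
  expect_equal(cat_of("BDNF"), "v")
})

test_that("the classifier is total and deterministic over the feature space", {
  grid <- tidyr::expand_grid(
    quantity_dir = c("up", "down"),
    quantity_sig = c(TRUE, FALSE),
    expr_hp_dir = c("up", "down"),
    expr_soma_dir = c("up", "down"),
    expr_soma_sig = c(TRUE, FALSE),
    tendency = c("decreasing", "increasing", "unordered"),
    level_rel = c("lower", "higher")
  )
  feats <- grid |>
    dplyr::mutate(
      gene_symbol = paste0("g", dplyr::row_number()),
      level_inoa = ifelse(level_rel == "lower", 20, 60),
      level_oa = 40,
      level_sig = TRUE,
      expr_hp_mag = "single", expr_hp_sig = FALSE,
      expr_soma_mag = "single"
    )
  ev <- classify_evidence(feats)
  expect_false(any(is.na(ev$category)))
  expect_true(all(as.character(ev$category) %in% c("i", "ii", "iii", "iv", "v")))
  expect_equal(ev$mechanism, ifelse(ev$category %in% c("iv", "v"), "Yes", "No"))
  # determinism
  expect_identical(ev$category, classify_evidence(feats)$category)
  # quantity up without level drop cannot be category i
  up_ns_higher <- ev |>
    dplyr::filter(quantity_dir == "up", !quantity_sig, level_rel == "higher")
  expect_true(all(up_ns_higher$category == "iii"))
})

test_that("incomplete feature tuples are rejected by name", {
  fx <- load_candidate_fixture()
  expect_error(classify_evidence(fx[, -3]), "missing")
  fx2 <- fx
  fx2$quantity_dir[3] <- NA
  expect_error(classify_evidence(fx2), fx2$gene_symbol[3])
})

test_that("extract_features errors when a gene lacks a contrast", {
  sim <- simulate_experiment(sim_config(n_genes = 4, noise_sigma = 0.1, seed = 3))
  quant <- quick_quant(sim)
  broken <- quant
  gene <- broken$gene_symbol[1]
  broken$quantity[broken$gene_symbol == gene &
                    grepl("^OA", broken$sample_id)] <- 0
  expect_error(extract_features(broken, sim$samples), gene)
})

test_that("pipeline features recover planted categories under noise", {
  # moderate-noise spot check; the full 200-seed recovery study lives in
  # the acceptance suite
  hits <- vapply(1:20, function(s) {
    sg <- single_gene_sim("v", effect_size = 4, noise_sigma = 0.15, seed = s)
    quant <- quick_quant(sg$sim)
    ev <- classify_evidence(extract_features(quant, sg$sim$samples))
    as.character(ev$category[ev$gene_symbol == sg$gene]) == "v"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
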