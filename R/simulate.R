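#' Configuration for a synthetic MeRIP-array experiment
#'
#' Builds a validated configuration for [simulate_experiment()]. The default
#' design mirrors the study layout the package targets: three histology
#' groups (OA control, then the HP and SOMA grades of impaired
#' spermatogenesis) with three biological replicates each, so nine samples,
#' each contributing one IP and one Sup channel.
#'
#' Each gene `g` in group `k` has a true methylation fraction
#' `m_gk` (the fraction of its transcript signal carried by the IP channel)
#' and a true total abundance `T_gk` in arbitrary intensity units. Planted
#' genes realise the evidence-category profiles of [planted_profile()];
#' unplanted genes are nulls with group-constant `m` and `T` drawn once per
#' gene, so the type-I behaviour of the downstream screen is measurable.
#'
#' @param n_genes Total number of non-spike-in genes (planted + null).
#' @param n_per_group Biological replicates per group (default 3).
#' @param planted Optional tibble of planted genes with columns
#'   `gene_symbol`, `category` and `m_OA`, `m_HP`, `m_SOMA`,
#'   `t_OA`, `t_HP`, `t_SOMA`. If `NULL`, a default cohort is planted so
#'   that `1 - null_fraction` of genes carry an effect, cycling through
#'   categories i-v at `effect_size`.
#' @param null_fraction Fraction of genes left as nulls when `planted` is
#'   `NULL` (default 0.9).
#' @param effect_size Effect size used for the default planted cohort.
#' @param noise_sigma Standard deviation of the multiplicative log-normal
#'   measurement noise, in log2 units (default 0.15).
#' @param n_spikeins Number of spike-in control probes.
#' @param spikein_level True intensity of every spike-in probe in both
#'   channels.
#' @param flag_low_quantile Per-sample expression quantile below which a
#'   probe is QC-flagged Absent.
#' @param flag_absent_rate Additional probability of a random Absent flag
#'   (dropout).
#' @param seed Integer seed; identical configurations give bit-identical
#'   simulations.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 7)
#' sim <- simulate_experiment(cfg)
#' sim$truth
sim_config <- function(n_genes = 1000,
                       n_per_group = 3,
                       planted = NULL,
                       null_fraction = 0.9,
                       effect_size = 4,
                       noise_sigma = 0.15,
                       n_spikeins = 10,
                       spikein_level = 1000,
                       flag_low_quantile = 0.02,
                       flag_absent_rate = 0.01,
                       seed = 1L) {
  stop_field <- function(field, msg) {
    abort(paste0("invalid sim_config field '", field, "': ", msg))
  }
  if (!is.numeric(n_genes) || n_genes < 1) stop_field("n_genes", "must be >= 1")
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    stop_field("n_per_group", "must be >= 2 so group contrasts are defined")
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop_field("noise_sigma", "must be >= 0")
  }
  if (!is.numeric(n_spikeins) || n_spikeins < 0) stop_field("n_spikeins", "must be >= 0")
  if (!is.numeric(spikein_level) || spikein_level <= 0) {
    stop_field("spikein_level", "must be > 0")
  }
  if (flag_low_quantile < 0 || flag_low_quantile > 1) {
    stop_field("flag_low_quantile", "must be in [0, 1]")
  }
  if (flag_absent_rate < 0 || flag_absent_rate > 1) {
    stop_field("flag_absent_rate", "must be in [0, 1]")
  }
  if (null_fraction < 0 || null_fraction > 1) {
    stop_field("null_fraction", "must be in [0, 1]")
  }
  if (is.null(planted)) {
    n_planted <- round((1 - null_fraction) * n_genes)
    planted <- default_planted_cohort(n_planted, effect_size)
  } else {
    planted <- as_tibble(planted)
    needed <- c(
      "gene_symbol", "category",
      paste0("m_", merip_groups()), paste0("t_", merip_groups())
    )
    missing <- setdiff(needed, names(planted))
    if (length(missing) > 0) {
      stop_field("planted", paste0("missing columns: ", paste(missing, collapse = ", ")))
    }
  }
  if (nrow(planted) > n_genes) stop_field("planted", "more planted genes than n_genes")
  m_cols <- as.matrix(planted[paste0("m_", merip_groups())])
  if (nrow(planted) > 0 && (any(m_cols <= 0) || any(m_cols >= 1))) {
    stop_field("planted", "methylation fractions m must lie strictly in (0, 1)")
  }
  t_cols <- as.matrix(planted[paste0("t_", merip_groups())])
  if (nrow(planted) > 0 && any(t_cols <= 0)) {
    stop_field("planted", "true abundances t must be > 0")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_per_group = as.integer(n_per_group),
      groups = merip_groups(),
      planted = planted,
      noise_sigma = noise_sigma,
      n_spikeins = as.integer(n_spikeins),
      spikein_level = spikein_level,
      flag_low_quantile = flag_low_quantile,
      flag_absent_rate = flag_absent_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

default_planted_cohort <- function(n_planted, effect_size) {
  cats <- c("i", "ii", "iii", "iv", "v")
  if (n_planted == 0) {
    return(planted_genes(character(0), effect_size))
  }
  planted_genes(rep(cats, length.out = n_planted), effect_size)
}

#' Group profiles realising an evidence category
#'
#' Returns noise-free per-group methylation fractions and abundances whose
#' derived feature tuple maps to the requested evidence category under
#' [classify_evidence()]. Category `null` gives identical parameters in all
#' groups.
#'
#' The profiles encode, per category: (i) lower methylation level in iNOA
#' with modestly increased m6A quantity and strongly increased expression;
#' (ii) significantly increased quantity; (iii) modestly decreased quantity
#' with discordant expression directions between HP/OA and SOMA/OA;
#' (iv) significantly decreased quantity and expression, but the SOMA/OA
#' expression change below the fold-change cutoff; (v) significantly
#' decreased quantity with expression falling monotonically across
#' OA, HP, SOMA and a significant SOMA/OA change.
#'
#' @param category One of `"i"`, `"ii"`, `"iii"`, `"iv"`, `"v"`, `"null"`.
#' @param effect_size Fold-scale effect (> 1) controlling how far the iNOA
#'   groups move from the OA baseline; default 4.
#' @param m_base OA-group methylation fraction baseline.
#' @param t_base OA-group abundance baseline (arbitrary intensity units).
#' @return A tibble with columns `group`, `m`, `t` (one row per group in
#'   the order OA, HP, SOMA).
#' @export
#' @examples
#' planted_profile("v", effect_size = 4)
planted_profile <- function(category, effect_size = 4,
                            m_base = 0.4, t_base = 100) {
  if (!is.character(category) || length(category) != 1 ||
      !category %in% c("i", "ii", "iii", "iv", "v", "null")) {
    abort("unknown evidence category; expected one of i, ii, iii, iv, v, null")
  }
  if (effect_size <= 1) abort("effect_size must be > 1")
  e <- effect_size
  prof <- switch(category,
    null = list(m = c(m_base, m_base, m_base), t = c(t_base, t_base, t_base)),
    # quantity drifts up but stays under the 2-fold cutoff; level collapses;
    # expression rises strongly (the MITF/PUM1 pattern).
    i = {
      m_i <- m_base / e
      t_i <- 1.5 * t_base * m_base / m_i # quantity x1.5, below cutoff
      list(m = c(m_base, m_i, m_i), t = c(t_base, t_i, t_i))
    },
    # quantity significantly up despite a halved level (the NPPB pattern).
    ii = {
      m_i <- m_base / 2
      t_i <- e * t_base * m_base / m_i # quantity x e >= cutoff
      list(m = c(m_base, m_i, m_i), t = c(t_base, t_i, t_i))
    },
    # quantity mildly down (under cutoff), expression discordant.
    iii = {
      m_i <- m_base * 0.75
      list(
        m = c(m_base, m_i, m_i),
        t = c(t_base, 1.2 * t_base, 0.8 * t_base)
      )
    },
    # quantity significantly down; expression down in both iNOA groups but
    # the SOMA/OA drop stays under the cutoff, hence non-significant.
    iv = {
      m_i <- m_base / 2
      list(
        m = c(m_base, m_i, m_i),
        t = c(t_base, t_base / e, t_base / 1.7)
      )
    },
    # quantity significantly down; expression falls monotonically with a
    # significant SOMA/OA change (the BDNF pattern).
    v = {
      m_oa <- 0.6
      list(
        m = c(m_oa, m_oa / 2, m_oa / e),
        t = c(t_base, t_base / 2.2, t_base / (e + 1))
      )
    }
  )
  tibble(group = merip_groups(), m = prof$m, t = prof$t)
}

#' Build a planted-gene table from category labels
#'
#' Convenience wrapper around [planted_profile()] producing the wide table
#' accepted by [sim_config()].
#'
#' @param categories Character vector of categories (repeats allowed).
#' @param effect_size Passed to [planted_profile()].
#' @param prefix Gene-symbol prefix for generated names.
#' @return Tibble with one row per planted gene.
#' @export
planted_genes <- function(categories, effect_size = 4, prefix = "PL") {
  rows <- purrr::imap(categories, function(cat, idx) {
    prof <- planted_profile(cat, effect_size)
    tibble(
      gene_symbol = sprintf("%s_%s_%03d", prefix, cat, idx),
      category = cat,
      m_OA = prof$m[1], m_HP = prof$m[2], m_SOMA = prof$m[3],
      t_OA = prof$t[1], t_HP = prof$t[2], t_SOMA = prof$t[3]
    )
  })
  if (length(rows) == 0) {
    return(tibble(
      gene_symbol = character(), category = character(),
      m_OA = double(), m_HP = double(), m_SOMA = double(),
      t_OA = double(), t_HP = double(), t_SOMA = double()
    ))
  }
  bind_rows(rows)
}

#' Simulate a MeRIP-array experiment with known ground truth
#'
#' Generates a probe-level two-channel intensity table, sample sheet and
#' truth table under the measurement model: for gene `g`, sample `s` in
#' group `k`,
#' \deqn{IP_{gs} = T_{gk}\, m_{gk}\, \varepsilon_{gs}, \qquad
#'       Sup_{gs} = T_{gk}\, (1 - m_{gk})\, \varepsilon'_{gs},}
#' with independent log-normal noise terms (`log2` standard deviation
#' `noise_sigma`) per channel. Spike-in probes have constant true intensity
#' `spikein_level` in both channels. QC flags are Absent when a probe's
#' total intensity falls below the configured per-sample quantile or by
#' random dropout, otherwise Present or (occasionally) Marginal.
#'
#' The same seed gives bit-identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `intensity` (wide probe-level table as read
#'   by [read_intensity_table()]), `samples` (sample sheet) and `truth`
#'   (per-gene planted parameters and category).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("config must be created with sim_config()")
  }
  groups <- config$groups
  n <- config$n_per_group
  sheet <- tibble(
    sample_id = paste0(rep(groups, each = n), rep(seq_len(n), times = length(groups))),
    group = factor(rep(groups, each = n), levels = groups),
    replicate = rep(seq_len(n), times = length(groups))
  )

  planted <- config$planted
  n_null <- config$n_genes - nrow(planted)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  null_truth <- if (n_null > 0) {
    m0 <- runif(n_null, 0.1, 0.9)
    t0 <- 2^rnorm(n_null, mean = 8, sd = 1.5)
    tibble(
      gene_symbol = sprintf("NULL_%05d", seq_len(n_null)),
      category = "null",
      m_OA = m0, m_HP = m0, m_SOMA = m0,
      t_OA = t0, t_HP = t0, t_SOMA = t0
    )
  } else {
    planted[0, ]
  }
  truth <- bind_rows(planted, null_truth)

  n_genes <- nrow(truth)
  n_samples <- nrow(sheet)
  m_mat <- as.matrix(truth[paste0("m_", merip_groups())])
  t_mat <- as.matrix(truth[paste0("t_", merip_groups())])
  grp_idx <- match(as.character(sheet$group), merip_groups())

  ip <- matrix(0, n_genes, n_samples)
  sup <- matrix(0, n_genes, n_samples)
  for (j in seq_len(n_samples)) {
    k <- grp_idx[j]
    mu_ip <- t_mat[, k] * m_mat[, k]
    mu_sup <- t_mat[, k] * (1 - m_mat[, k])
    ip[, j] <- mu_ip * 2^rnorm(n_genes, 0, config$noise_sigma)
    sup[, j] <- mu_sup * 2^rnorm(n_genes, 0, config$noise_sigma)
  }

  n_spk <- config$n_spikeins
  if (n_spk > 0) {
    spk_ip <- config$spikein_level *
      matrix(2^rnorm(n_spk * n_samples, 0, config$noise_sigma), n_spk, n_samples)
    spk_sup <- config$spikein_level *
      matrix(2^rnorm(n_spk * n_samples, 0, config$noise_sigma), n_spk, n_samples)
  } else {
    spk_ip <- spk_sup <- matrix(0, 0, n_samples)
  }

  all_ip <- rbind(ip, spk_ip)
  all_sup <- rbind(sup, spk_sup)
  probe_ids <- c(paste0("p_", truth$gene_symbol), sprintf("SPK%03d", seq_len(n_spk)))
  gene_syms <- c(truth$gene_symbol, sprintf("SPK%03d", seq_len(n_spk)))
  is_spk <- c(rep(FALSE, n_genes), rep(TRUE, n_spk))

  flags <- matrix("P", nrow(all_ip), n_samples)
  for (j in seq_len(n_samples)) {
    tot <- all_ip[, j] + all_sup[, j]
    lo <- quantile(tot[!is_spk], config$flag_low_quantile, names = FALSE)
    u <- runif(nrow(all_ip))
    absent <- (!is_spk) & (tot < lo | u < config$flag_absent_rate)
    marginal <- (!is_spk) & !absent & (runif(nrow(all_ip)) < 0.1)
    flags[absent, j] <- "A"
    flags[marginal, j] <- "M"
  }

  out <- tibble(probe_id = probe_ids, gene_symbol = gene_syms, is_spikein = is_spk)
  for (j in seq_len(n_samples)) {
    s <- sheet$sample_id[j]
    out[[paste0("IP_", s)]] <- all_ip[, j]
    out[[paste0("Sup_", s)]] <- all_sup[, j]
    out[[paste0("flag_", s)]] <- flags[, j]
  }

  list(
    intensity = new_intensity_table(out),
    samples = sheet,
    truth = truth
  )
}
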