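#' Spike-in normalisation
#'
#' Rescales every sample x channel by a single factor so that the median
#' spike-in intensity in that sample and channel equals `target`. Relative
#' structure among probes within a channel is preserved exactly (the
#' operation is a per-column scalar multiplication), so the derived
#' methylation level of any probe is unchanged when IP and Sup happen to be
#' rescaled by the same factor, and cross-array intensity scales are made
#' comparable.
#'
#' @param table Intensity table with at least one spike-in probe.
#' @param target Target median spike-in intensity. Default (`NULL`) is the
#'   median of the per-sample/channel spike-in medians, which preserves the
#'   overall intensity scale of the experiment.
#' @return The rescaled intensity table, plus attributes `spikein_target`
#'   and `spikein_factors` (the per-sample/channel scale factors applied).
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 20, seed = 1))
#' norm <- normalize_spikein(sim$intensity)
#' attr(norm, "spikein_target")
normalize_spikein <- function(table, target = NULL) {
  samples <- intensity_samples(table)
  spk <- table$is_spikein
  if (!any(spk)) {
    abort("spike-in normalization failed: table contains no spike-in probes")
  }
  medians <- expand.grid(
    sample_id = samples, channel = c("IP", "Sup"),
    stringsAsFactors = FALSE
  )
  medians$median <- purrr::map2_dbl(
    medians$sample_id, medians$channel,
    function(s, ch) median(table[[paste0(ch, "_", s)]][spk])
  )
  if (any(!is.finite(medians$median) | medians$median <= 0)) {
    bad <- medians[!is.finite(medians$median) | medians$median <= 0, ][1, ]
    abort(paste0(
      "spike-in normalization failed: non-positive spike-in median in sample ",
      bad$sample_id, ", channel ", bad$channel
    ))
  }
  if (is.null(target)) target <- median(medians$median)
  if (!is.numeric(target) || target <= 0) {
    abort("spike-in target must be a positive intensity")
  }
  medians$factor <- target / medians$median
  out <- table
  for (i in seq_len(nrow(medians))) {
    col <- paste0(medians$channel[i], "_", medians$sample_id[i])
    out[[col]] <- out[[col]] * medians$factor[i]
  }
  attr(out, "spikein_target") <- target
  attr(out, "spikein_factors") <- as_tibble(medians)
  out
}

#' QC retention filter ("All Targets Value")
#'
#' Retains probes whose QC flag is Present (P) or Marginal (M) in at least
#' `min_pm` samples; with the default `min_pm = 3` on a nine-sample design
#' this is the "at least 3 out of 9" retention rule. Flags are per sample
#' (one flag covers both channels). Spike-in probes are always retained for
#' audit; downstream quantification excludes them regardless.
#'
#' @param table Intensity table with flag columns populated.
#' @param min_pm Minimum number of P/M flags required (default 3).
#' @return The filtered intensity table, with an attribute `qc_n_dropped`.
#' @export
qc_filter <- function(table, min_pm = 3) {
  samples <- intensity_samples(table)
  if (min_pm > length(samples)) {
    abort(paste0(
      "qc_filter: min_pm (", min_pm, ") exceeds the number of samples (",
      length(samples), ")"
    ))
  }
  flag_cols <- paste0("flag_", samples)
  n_pm <- rowSums(sapply(flag_cols, function(col) table[[col]] %in% c("P", "M")))
  keep <- n_pm >= min_pm | table$is_spikein
  out <- table[keep, ]
  attr(out, "qc_n_dropped") <- sum(!keep)
  out
}
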