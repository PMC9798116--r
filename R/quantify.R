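#' m6A methylation level from paired channel intensities
#'
#' The methylation level of a transcript is the percentage of its total
#' signal carried by the immunoprecipitated (modified) fraction:
#' `100 * IP / (IP + Sup)`. It is invariant under joint rescaling of both
#' channels and complementary under channel swap
#' (`methylation_level(a, b) + methylation_level(b, a) == 100`).
#'
#' @param ip Non-negative IP-channel intensity (vectorised).
#' @param sup Non-negative Sup-channel intensity.
#' @return Percentage in `[0, 100]`; `NA` (with a warning) where
#'   `ip + sup == 0`, since the level is undefined there.
#' @export
#' @examples
#' methylation_level(50, 50) # 50
#' methylation_level(32.7, 67.3) # 32.7
methylation_level <- function(ip, sup) {
  if (any(ip < 0, na.rm = TRUE) || any(sup < 0, na.rm = TRUE)) {
    abort("methylation_level: intensities must be non-negative")
  }
  tot <- ip + sup
  out <- ifelse(tot > 0, 100 * ip / tot, NA_real_)
  if (any(tot == 0, na.rm = TRUE)) {
    warn("methylation_level undefined (IP + Sup = 0) for some probes; returning NA")
  }
  out
}

#' Per-gene, per-sample derived measures
#'
#' Computes the three measures of a two-channel m6A array per gene and
#' sample, from a normalised and QC-filtered intensity table:
#'
#' * **level** — m6A methylation level, `100 * IP / (IP + Sup)` (percent);
#' * **quantity** — m6A quantity, the normalised IP intensity;
#' * **expression** — expression level, the total `IP + Sup` intensity.
#'
#' Genes measured by several probes are aggregated channel-first: probe
#' intensities are combined per channel per sample with `aggregate`
#' (median by default) and the level is then formed from the aggregated
#' channels — not by averaging per-probe levels.
#'
#' @param table Normalised, QC-filtered intensity table. Spike-in probes
#'   are excluded.
#' @param sheet Optional sample sheet; if supplied, samples are checked
#'   against it and carried as an attribute for downstream group summaries.
#' @param aggregate Probe-to-gene aggregation rule: `"median"`, `"mean"` or
#'   `"sum"` of probe intensities per channel.
#' @return A tibble of class `merip_quant`, one row per gene x sample, with
#'   columns `gene_symbol`, `sample_id`, `level`, `quantity`, `expression`.
#' @export
compute_quant_table <- function(table, sheet = NULL,
                                aggregate = c("median", "mean", "sum")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- switch(aggregate, median = median, mean = mean, sum = sum)
  genes <- table[!table$is_spikein, ]
  if (nrow(genes) == 0) {
    abort("compute_quant_table: no non-spike-in probes in table")
  }
  if (!is.null(sheet)) check_samples(table, sheet)
  long <- intensity_long(genes) |>
    group_by(.data$gene_symbol, .data$sample_id) |>
    summarise(
      IP = agg_fun(.data$IP), Sup = agg_fun(.data$Sup),
      .groups = "drop"
    )
  dead <- long |>
    group_by(.data$gene_symbol) |>
    summarise(total = sum(.data$IP + .data$Sup), .groups = "drop") |>
    filter(.data$total == 0)
  if (nrow(dead) > 0) {
    abort(paste0(
      "compute_quant_table: gene with zero total intensity in all samples: ",
      dead$gene_symbol[[1]]
    ))
  }
  out <- long |>
    mutate(
      level = suppressWarnings(methylation_level(.data$IP, .data$Sup)),
      quantity = .data$IP,
      expression = .data$IP + .data$Sup
    ) |>
    select("gene_symbol", "sample_id", "level", "quantity", "expression") |>
    arrange(.data$gene_symbol, .data$sample_id)
  class(out) <- c("merip_quant", class(out))
  attr(out, "samples") <- if (!is.null(sheet)) sheet else NULL
  out
}

#' Group summaries of a derived measure
#'
#' Per-gene group means of one of the three measures, in the fixed group
#' order OA, HP, SOMA. Intensity-scale measures (`quantity`, `expression`)
#' are summarised with the geometric mean, consistent with fold changes
#' computed on the log2 scale; `level` (a percentage) with the arithmetic
#' mean.
#'
#' @param quant A `merip_quant` table.
#' @param sheet Sample sheet.
#' @param measure One of `"level"`, `"quantity"`, `"expression"`.
#' @return Tibble `gene_symbol`, `group`, `mean`, with `group` ordered.
#' @export
group_means <- function(quant, sheet, measure = c("expression", "level", "quantity")) {
  measure <- match.arg(measure)
  geometric <- measure != "level"
  quant |>
    inner_join(sheet, by = "sample_id") |>
    group_by(.data$gene_symbol, .data$group) |>
    summarise(
      mean = if (geometric) {
        2^mean(log2(.data[[measure]]))
      } else {
        mean(.data[[measure]])
      },
      .groups = "drop"
    )
}
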