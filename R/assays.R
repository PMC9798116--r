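#' Relative expression by the 2^-dCt method
#'
#' Relative expression of a target transcript against an internal reference
#' (e.g. GAPDH) from qPCR threshold cycles: `2^-(Ct_target - Ct_reference)`.
#' Technical duplicates should be averaged (arithmetic mean of Ct values)
#' before applying the formula; [qpcr_relative_expression()] does this for
#' well-level tables.
#'
#' @param ct_target Threshold cycle(s) of the target gene.
#' @param ct_reference Threshold cycle(s) of the reference gene.
#' @return Relative expression, strictly decreasing in `ct_target`.
#' @export
#' @examples
#' ddct_relative_expression(25, 25) # 1
#' ddct_relative_expression(26, 25) # 0.5
ddct_relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    abort("ddct_relative_expression: Ct values must be finite")
  }
  2^(-(ct_target - ct_reference))
}

#' Relative expression from a well-level Ct table
#'
#' Averages technical replicate wells per sample x gene, then computes
#' `2^-dCt` of each gene against the reference gene within each sample.
#'
#' @param ct_table Data frame with columns `sample_id`, `gene`, `ct`
#'   (one row per well).
#' @param reference Reference gene symbol (default `"GAPDH"`).
#' @return Tibble `sample_id`, `gene`, `ct_mean`, `relative_expression`
#'   (reference gene rows excluded).
#' @export
qpcr_relative_expression <- function(ct_table, reference = "GAPDH") {
  needed <- c("sample_id", "gene", "ct")
  missing <- setdiff(needed, names(ct_table))
  if (length(missing) > 0) {
    abort(paste0("ct_table missing columns: ", paste(missing, collapse = ", ")))
  }
  means <- ct_table |>
    group_by(.data$sample_id, .data$gene) |>
    summarise(ct_mean = mean(.data$ct), .groups = "drop")
  ref <- means |>
    filter(.data$gene == reference) |>
    select("sample_id", ct_ref = "ct_mean")
  if (nrow(ref) == 0) {
    abort(paste0("reference gene '", reference, "' absent from ct_table"))
  }
  means |>
    filter(.data$gene != reference) |>
    inner_join(ref, by = "sample_id") |>
    mutate(relative_expression = ddct_relative_expression(.data$ct_mean, .data$ct_ref)) |>
    select("sample_id", "gene", "ct_mean", "relative_expression")
}

#' Percent m6A from a colorimetric ELISA plate
#'
#' Kit-convention slope-ratio quantification of global m6A from OD450
#' readings: the blank-corrected signal per nanogram of sample RNA is
#' divided by the blank-corrected signal per nanogram of the positive
#' control,
#' \deqn{\%m^6A = \frac{(OD_{sample} - OD_{NC}) / S}{(OD_{PC} - OD_{NC}) / P}
#'       \times 100,}
#' where `S` is the sample RNA input (default 200 ng) and `P` the positive
#' control amount. Negative blank-corrected signals are clipped to zero
#' with a warning.
#'
#' @param od_sample OD450 of the test well(s).
#' @param od_nc OD450 of the negative control.
#' @param od_pc OD450 of the positive control; must exceed `od_nc`.
#' @param s_ng Sample RNA input in ng (default 200).
#' @param p_ng Positive-control amount in ng (kit-specific, required).
#' @return Percent m6A (>= 0), linear in `od_sample - od_nc`.
#' @export
#' @examples
#' elisa_m6a_percent(0.6, 0.1, 1.1, s_ng = 200, p_ng = 200) # 50
elisa_m6a_percent <- function(od_sample, od_nc, od_pc, s_ng = 200, p_ng) {
  if (any(od_pc <= od_nc)) {
    abort("elisa_m6a_percent: calibration error, od_pc must exceed od_nc")
  }
  if (any(s_ng <= 0) || any(p_ng <= 0)) {
    abort("elisa_m6a_percent: RNA amounts must be positive")
  }
  num <- od_sample - od_nc
  if (any(num < 0)) {
    warn("elisa_m6a_percent: negative blank-corrected OD clipped to 0")
    num <- pmax(num, 0)
  }
  (num / s_ng) / ((od_pc - od_nc) / p_ng) * 100
}
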