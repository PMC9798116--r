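#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a comparison result
#'
#' Returns the per-gene contrast table with the arrow/star coding
#' appended.
#'
#' @param x A `merip_comparison` tibble.
#' @param ... Unused.
#' @return A tibble with an additional `arrow` column.
#' @method tidy merip_comparison
#' @export
tidy.merip_comparison <- function(x, ...) {
  thr <- attr(x, "double_threshold") %||% 2
  as_tibble(x) |>
    mutate(arrow = arrow_code(.data$direction, .data$fc, .data$significant, thr))
}

#' Summarise a comparison result
#'
#' One row per measure x contrast with gene counts and screen settings.
#'
#' @param x A `merip_comparison` tibble.
#' @param ... Unused.
#' @return A one-row-per-contrast tibble: `measure`, `contrast`,
#'   `n_genes`, `n_tested`, `n_significant`, `n_up_sig`, `n_down_sig`,
#'   `alpha`, `fc_cutoff`, `method`.
#' @method glance merip_comparison
#' @export
glance.merip_comparison <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$measure, .data$contrast) |>
    summarise(
      n_genes = n(),
      n_tested = sum(!is.na(.data$p)),
      n_significant = sum(.data$significant),
      n_up_sig = sum(.data$significant & .data$direction == "up", na.rm = TRUE),
      n_down_sig = sum(.data$significant & .data$direction == "down", na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(
      alpha = attr(x, "alpha") %||% NA_real_,
      fc_cutoff = attr(x, "fc_cutoff") %||% NA_real_,
      method = attr(x, "method") %||% NA_character_
    )
}

#' Tidy an evidence table
#'
#' @param x A `merip_evidence` tibble.
#' @param ... Unused.
#' @return Tibble `gene_symbol`, `category`, `mechanism`.
#' @method tidy merip_evidence
#' @export
tidy.merip_evidence <- function(x, ...) {
  as_tibble(x) |> select("gene_symbol", "category", "mechanism")
}

#' Summarise an evidence table
#'
#' @param x A `merip_evidence` tibble.
#' @param ... Unused.
#' @return One-row tibble with per-category gene counts and the number of
#'   mechanism calls.
#' @method glance merip_evidence
#' @export
glance.merip_evidence <- function(x, ...) {
  counts <- table(x$category)
  bind_cols(
    tibble(n_genes = nrow(x)),
    as_tibble(as.list(stats::setNames(
      as.integer(counts), paste0("n_", names(counts))
    ))),
    tibble(n_mechanism_yes = sum(x$mechanism == "Yes"))
  )
}

#' Volcano plot of a comparison result
#'
#' @param object A `merip_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot: log2 fold change against -log10 p, significant genes
#'   highlighted, with the fold-change cutoff and alpha drawn as guides.
#' @method autoplot merip_comparison
#' @export
autoplot.merip_comparison <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  fc_cutoff <- attr(object, "fc_cutoff") %||% 2
  df <- as_tibble(object) |> filter(!is.na(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$p), colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(
      xintercept = c(-log2(fc_cutoff), log2(fc_cutoff)), linetype = "dashed"
    ) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 fold change", y = expression(-log[10] ~ p),
      colour = "significant",
      title = paste(unique(df$measure), unique(df$contrast), collapse = "; ")
    ) +
    ggplot2::theme_minimal()
}

#' Per-sample distribution of a derived measure
#'
#' @param object A `merip_quant` tibble.
#' @param measure Which measure to draw (default `"level"`).
#' @param sheet Optional sample sheet used to colour samples by group; the
#'   sheet attached by [compute_quant_table()] is used when present.
#' @param ... Unused.
#' @return A ggplot of per-sample boxplots.
#' @method autoplot merip_quant
#' @export
autoplot.merip_quant <- function(object, measure = c("level", "quantity", "expression"),
                                 sheet = NULL, ...) {
  measure <- match.arg(measure)
  sheet <- sheet %||% attr(object, "samples")
  df <- as_tibble(object)
  if (!is.null(sheet)) {
    df <- df |> inner_join(sheet, by = "sample_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$sample_id, y = .data[[measure]], fill = .data$group
    ))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data[[measure]]))
  }
  p +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(
      x = NULL,
      y = if (measure == "level") "m6A methylation level (%)" else measure
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Evidence category counts
#'
#' @param object A `merip_evidence` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of genes per evidence category, mechanism
#'   calls highlighted.
#' @method autoplot merip_evidence
#' @export
autoplot.merip_evidence <- function(object, ...) {
  df <- as_tibble(object) |> count(.data$category, .data$mechanism)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$category, y = .data$n, fill = .data$mechanism
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(No = "grey70", Yes = "firebrick")) +
    ggplot2::labs(
      x = "evidence category", y = "genes",
      fill = "mechanism"
    ) +
    ggplot2::theme_minimal()
}

#' Venn region counts of a set intersection
#'
#' @param object A `merip_setops` result.
#' @param ... Unused.
#' @return A ggplot bar chart of exclusive Venn region counts.
#' @method autoplot merip_setops
#' @export
autoplot.merip_setops <- function(object, ...) {
  ggplot2::ggplot(object$regions, ggplot2::aes(
    x = stats::reorder(.data$region, -.data$count), y = .data$count
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Venn region", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
print.merip_setops <- function(x, ...) {
  cat("Gene-set intersection of", length(x$sets), "sets:",
      paste(names(x$sets), collapse = ", "), "\n")
  cat("Intersection size:", length(x$intersection), "\n")
  print(x$regions)
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("MeRIP-array simulation config:\n")
  cat("  genes:", x$n_genes, "(", nrow(x$planted), "planted )\n")
  cat("  design:", length(x$groups), "groups x", x$n_per_group, "replicates\n")
  cat("  noise_sigma (log2):", x$noise_sigma, "; spike-ins:", x$n_spikeins, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
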