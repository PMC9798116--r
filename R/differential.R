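#' Two-sample group comparison p-value
#'
#' The per-gene test behind all group contrasts. `t_welch` (default) is the
#' Welch unequal-variance two-sample t test; `mannwhitney` is the two-sided
#' Mann-Whitney U test, using the exact null distribution when the combined
#' sample size is at most 16 and there are no ties, and the tie-corrected
#' normal approximation (with continuity correction) otherwise.
#'
#' Degenerate inputs are resolved deterministically rather than erroring:
#' if every value in both groups is identical the evidence for a difference
#' is nil and `p = 1`; if both groups are internally constant but differ,
#' the groups are perfectly separated with zero variance and `p = 0` (the
#' limit of the Welch statistic as within-group variance vanishes).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param method `"t_welch"` or `"mannwhitney"`.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
#' @examples
#' group_test(c(1, 2, 3), c(10, 11, 12), method = "mannwhitney") # 0.1
group_test <- function(values_a, values_b, method = c("t_welch", "mannwhitney")) {
  method <- match.arg(method)
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("group_test: each group needs at least 2 values")
  }
  if (any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    abort("group_test: values must be finite")
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1) {
    return(1)
  }
  if (method == "t_welch") {
    if (sd(values_a) == 0 && sd(values_b) == 0) {
      # internally constant but different groups: perfect separation
      return(0)
    }
    return(t.test(values_a, values_b, var.equal = FALSE)$p.value)
  }
  ties <- any(duplicated(pooled))
  exact <- !ties && length(pooled) <= 16
  res <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE)
  )
  unname(res$p.value)
}

#' Per-gene group contrast of a derived measure
#'
#' Contrasts one measure between two groups for every gene. The fold change
#' is the ratio of geometric means on the linear scale, i.e.
#' `2^(mean(log2 A) - mean(log2 B))`; the p-value comes from [group_test()]
#' applied to the log2 values. A gene is flagged significant when `p <
#' alpha` and — for the intensity-scale screens (`quantity`,
#' `expression`) — the fold change is at least `fc_cutoff` or at most
#' `1/fc_cutoff`. Level contrasts carry no fold-change cutoff: the
#' methylation level is a bounded percentage and its significance is the
#' test alone.
#'
#' @param quant A `merip_quant` table from [compute_quant_table()].
#' @param sheet Sample sheet.
#' @param measure `"level"`, `"quantity"` or `"expression"`.
#' @param contrast Either a string `"A/B"` (e.g. `"SOMA/OA"`) or a
#'   length-2 character vector `c(A, B)`. The pooled label `"iNOA"`
#'   denotes all HP and SOMA samples together.
#' @param alpha Significance level (default 0.05).
#' @param fc_cutoff Fold-change cutoff applied to quantity/expression
#'   screens (default 2).
#' @param method Test passed to [group_test()].
#' @param double_threshold Fold change at and beyond which the magnitude
#'   class is `"double"` (double arrow) rather than `"single"`; default 2.
#' @return A tibble of class `merip_comparison` with one row per gene:
#'   `gene_symbol`, `measure`, `contrast`, `fc`, `log2fc`, `direction`,
#'   `magnitude`, `p`, `significant`. Genes with missing or non-positive
#'   values in a group carry `NA` statistics and `significant = FALSE`.
#' @export
compare_groups <- function(quant, sheet,
                           measure = c("expression", "level", "quantity"),
                           contrast = "SOMA/OA",
                           alpha = 0.05, fc_cutoff = 2,
                           method = c("t_welch", "mannwhitney"),
                           double_threshold = 2) {
  measure <- match.arg(measure)
  method <- match.arg(method)
  groups <- parse_contrast(contrast)
  label <- paste0(groups$a_label, "/", groups$b_label)

  joined <- quant |>
    inner_join(sheet, by = "sample_id") |>
    mutate(group = as.character(.data$group))
  a_vals <- joined |> filter(.data$group %in% groups$a)
  b_vals <- joined |> filter(.data$group %in% groups$b)
  if (nrow(a_vals) == 0 || nrow(b_vals) == 0) {
    abort(paste0("compare_groups: contrast ", label, " has an empty group"))
  }

  per_gene <- function(vals) {
    split(vals[[measure]], vals$gene_symbol)
  }
  a_split <- per_gene(a_vals)
  b_split <- per_gene(b_vals)
  genes <- sort(union(names(a_split), names(b_split)))

  rows <- purrr::map_dfr(genes, function(g) {
    a <- a_split[[g]]
    b <- b_split[[g]]
    ok <- !is.null(a) && !is.null(b) &&
      sum(is.finite(a) & a > 0) >= 2 && sum(is.finite(b) & b > 0) >= 2
    if (!ok) {
      return(tibble(
        gene_symbol = g, fc = NA_real_, log2fc = NA_real_,
        direction = NA_character_, magnitude = NA_character_,
        p = NA_real_, significant = FALSE
      ))
    }
    la <- log2(a[is.finite(a) & a > 0])
    lb <- log2(b[is.finite(b) & b > 0])
    log2fc <- mean(la) - mean(lb)
    fc <- 2^log2fc
    p <- group_test(la, lb, method = method)
    passes_fc <- if (measure == "level") TRUE else (fc >= fc_cutoff || fc <= 1 / fc_cutoff)
    tibble(
      gene_symbol = g,
      fc = fc,
      log2fc = log2fc,
      direction = if (log2fc > 0) "up" else "down",
      magnitude = if (max(fc, 1 / fc) >= double_threshold) "double" else "single",
      p = p,
      significant = p < alpha && passes_fc
    )
  })
  out <- rows |>
    mutate(measure = measure, contrast = label, .after = "gene_symbol")
  class(out) <- c("merip_comparison", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "fc_cutoff") <- fc_cutoff
  attr(out, "method") <- method
  attr(out, "double_threshold") <- double_threshold
  out
}

parse_contrast <- function(contrast) {
  if (is.character(contrast) && length(contrast) == 1 && grepl("/", contrast)) {
    contrast <- strsplit(contrast, "/", fixed = TRUE)[[1]]
  }
  if (length(contrast) != 2) {
    abort("contrast must be 'A/B' or c(A, B)")
  }
  expand <- function(g) {
    if (identical(g, "iNOA")) inoa_groups() else g
  }
  allowed <- c(merip_groups(), "iNOA")
  bad <- setdiff(contrast, allowed)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown contrast group '", bad[[1]], "' (allowed: ",
      paste(allowed, collapse = ", "), ")"
    ))
  }
  list(
    a = expand(contrast[[1]]), b = expand(contrast[[2]]),
    a_label = contrast[[1]], b_label = contrast[[2]]
  )
}

#' Arrow coding of a fold change
#'
#' Encodes direction, magnitude and significance of a contrast in the
#' compact arrow notation used in candidate-gene tables: a single arrow for
#' fold changes below `double_threshold` (in either direction), a double
#' arrow at or beyond it, and a trailing `*` when the change is
#' statistically significant.
#'
#' @param direction `"up"` or `"down"` (vectorised).
#' @param fc Linear fold change (> 0).
#' @param significant Logical.
#' @param double_threshold Fold change at which the double arrow starts
#'   (default 2, the screening cutoff).
#' @return Character vector of arrow strings, e.g. `"\u2191"`,
#'   `"\u2193\u2193*"`.
#' @export
#' @examples
#' arrow_code("up", 1.5, FALSE) # single up arrow
#' arrow_code("down", 4, TRUE) # double down arrow, starred
arrow_code <- function(direction, fc, significant, double_threshold = 2) {
  n <- max(length(direction), length(fc), length(significant))
  direction <- rep_len(direction, n)
  fc <- rep_len(fc, n)
  significant <- rep_len(significant, n)
  purrr::pmap_chr(
    list(direction, fc, significant),
    function(d, f, s) {
      if (is.na(d) || is.na(f)) return(NA_character_)
      glyph <- if (d == "up") "\u2191" else "\u2193"
      mag <- if (max(f, 1 / f) >= double_threshold) 2 else 1
      paste0(strrep(glyph, mag), if (isTRUE(s)) "*" else "")
    }
  )
}

#' Parse an arrow token back to its components
#'
#' Inverse of [arrow_code()] up to the magnitude class: `"\u2191\u2191*"`
#' parses to direction `up`, magnitude `double`, significant `TRUE`.
#'
#' @param token Character vector of arrow tokens.
#' @return Tibble with columns `direction`, `magnitude`, `significant`.
#' @export
parse_arrow <- function(token) {
  purrr::map_dfr(token, function(tk) {
    m <- regmatches(tk, regexec("^(\u2191{1,2}|\u2193{1,2})(\\*?)$", tk))[[1]]
    if (length(m) == 0) {
      abort(paste0("unparseable arrow token: '", tk, "'"))
    }
    arrows <- m[[2]]
    tibble(
      direction = if (startsWith(arrows, "\u2191")) "up" else "down",
      magnitude = if (nchar(arrows) == 2) "double" else "single",
      significant = m[[3]] == "*"
    )
  })
}

#' Ordered tendency across the three groups
#'
#' Classifies the trajectory of per-group means in the fixed severity order
#' OA, HP, SOMA: `decreasing` when OA >= HP >= SOMA with OA > SOMA strictly
#' (the interior inequality is non-strict), `increasing` symmetrically, and
#' `unordered` otherwise. A gradually decreasing expression tendency across
#' the groups mirrors progressively impaired spermatogenesis and is the
#' distinguishing requirement of the strongest evidence category.
#'
#' @param oa,hp,soma Group means (vectorised).
#' @return Character vector in `{"decreasing", "increasing", "unordered"}`.
#' @export
#' @examples
#' tendency(10, 7, 3) # decreasing
#' tendency(10, 12, 3) # unordered
#' tendency(10, 10, 4) # decreasing (non-strict interior)
tendency <- function(oa, hp, soma) {
  if (any(!is.finite(c(oa, hp, soma)))) {
    abort("tendency: group means must be finite")
  }
  dplyr::case_when(
    oa >= hp & hp >= soma & oa > soma ~ "decreasing",
    oa <= hp & hp <= soma & oa < soma ~ "increasing",
    TRUE ~ "unordered"
  )
}
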