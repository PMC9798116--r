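#' Intersect named gene sets with Venn region counts
#'
#' Exact set intersection of two or more named gene sets, plus the
#' cardinality of every exclusive Venn region — the machine-readable
#' counterpart of the Venn diagrams used to nominate shared up-/
#' down-regulated and hypomethylated gene sets. Gene identity is the
#' symbol string, compared case-sensitively after whitespace trimming;
#' duplicate symbols within a set are collapsed with a warning.
#'
#' @param named_sets Named list of character vectors (2 or more sets).
#' @return A list of class `merip_setops` with elements
#'   `intersection` (sorted character vector common to all sets) and
#'   `regions` (tibble `region`, `count` over all non-empty membership
#'   patterns, e.g. `"A&B"`; counts are exclusive and partition the
#'   union).
#' @export
#' @examples
#' intersect_sets(list(up_HP = c("A", "B", "C"), up_SOMA = c("B", "C", "D")))
intersect_sets <- function(named_sets) {
  if (!is.list(named_sets) || length(named_sets) < 2) {
    abort("intersect_sets: need a named list of at least two sets")
  }
  if (is.null(names(named_sets)) || any(names(named_sets) == "")) {
    abort("intersect_sets: every set must be named")
  }
  sets <- purrr::imap(named_sets, function(x, nm) {
    x <- trimws(as.character(x))
    x <- x[x != ""]
    if (anyDuplicated(x)) {
      warn(paste0("intersect_sets: duplicate symbols collapsed in set '", nm, "'"))
      x <- unique(x)
    }
    x
  })
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  regions <- tibble(gene = universe, region = pattern) |>
    count(.data$region, name = "count") |>
    arrange(.data$region)
  inter <- universe[rowSums(membership) == length(sets)]
  structure(
    list(intersection = inter, regions = regions, sets = sets),
    class = "merip_setops"
  )
}

#' Significant gene set from a comparison result
#'
#' Convenience filter: the symbols significant in a given direction in a
#' `merip_comparison` table, ready for [intersect_sets()].
#'
#' @param comparison A `merip_comparison` tibble.
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene symbols.
#' @export
significant_genes <- function(comparison, direction = c("up", "down")) {
  direction <- match.arg(direction)
  comparison$gene_symbol[
    comparison$significant & !is.na(comparison$direction) &
      comparison$direction == direction
  ]
}
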