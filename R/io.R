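#' Read a probe-level intensity table
#'
#' Reads the tab-delimited interchange format for two-channel m6A array
#' intensities: one row per probe with columns `probe_id`, `gene_symbol`,
#' optionally `is_spikein`, and for every sample `s` the triple
#' `IP_<s>` (immunoprecipitated-fraction intensity), `Sup_<s>`
#' (supernatant-fraction intensity) and `flag_<s>` (QC flag, one of
#' `P`/`M`/`A` for Present/Marginal/Absent). Intensities are linear and
#' non-negative.
#'
#' If the file carries no `is_spikein` column, spike-in control probes are
#' identified by an explicit `spikeins` list (takes precedence) or by a
#' `spikein_prefix` on the probe id.
#'
#' @param path Path to a tab-delimited intensity file.
#' @param spikeins Optional character vector of probe ids to mark as
#'   spike-in controls.
#' @param spikein_prefix Probe-id prefix identifying spike-ins when no
#'   explicit list or `is_spikein` column is available.
#' @return A tibble of class `merip_intensity` with columns `probe_id`,
#'   `gene_symbol`, `is_spikein`, then `IP_<s>`, `Sup_<s>`, `flag_<s>` per
#'   sample.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' sim <- simulate_experiment(sim_config(n_genes = 5, n_spikeins = 2, seed = 1))
#' write_intensity_table(sim$intensity, tf)
#' read_intensity_table(tf)
read_intensity_table <- function(path, spikeins = NULL, spikein_prefix = "SPK") {
  if (!file.exists(path)) {
    abort(paste0("intensity table not found: ", path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("probe_id", "gene_symbol")) {
    if (!col %in% names(raw)) {
      abort(paste0("intensity table ", path, ": missing required column '", col, "'"))
    }
  }
  raw$probe_id <- as.character(raw$probe_id)
  raw$gene_symbol <- as.character(raw$gene_symbol)
  if (!"is_spikein" %in% names(raw)) {
    raw$is_spikein <- if (!is.null(spikeins)) {
      raw$probe_id %in% spikeins
    } else {
      startsWith(raw$probe_id, spikein_prefix)
    }
  } else if (!is.null(spikeins)) {
    raw$is_spikein <- raw$probe_id %in% spikeins
  }
  raw$is_spikein <- as.logical(raw$is_spikein)
  tbl <- as_tibble(raw[c(
    "probe_id", "gene_symbol", "is_spikein",
    setdiff(names(raw), c("probe_id", "gene_symbol", "is_spikein"))
  )])
  validate_intensity_table(tbl, context = path)
  new_intensity_table(tbl)
}

new_intensity_table <- function(tbl) {
  class(tbl) <- c("merip_intensity", class(tbl)[!class(tbl) %in% "merip_intensity"])
  tbl
}

#' Sample identifiers declared by an intensity table
#'
#' @param table An intensity table as returned by [read_intensity_table()] or
#'   [simulate_experiment()].
#' @return Character vector of sample ids, in column order.
#' @export
intensity_samples <- function(table) {
  sub("^IP_", "", grep("^IP_", names(table), value = TRUE))
}

validate_intensity_table <- function(tbl, context = "intensity table") {
  samples <- sub("^IP_", "", grep("^IP_", names(tbl), value = TRUE))
  if (length(samples) == 0) {
    abort(paste0(context, ": no IP_<sample> intensity columns found"))
  }
  for (s in samples) {
    for (col in paste0(c("Sup_", "flag_"), s)) {
      if (!col %in% names(tbl)) {
        abort(paste0(context, ": missing column '", col, "' paired with IP_", s))
      }
    }
  }
  dup <- tbl$probe_id[duplicated(tbl$probe_id)]
  if (length(dup) > 0) {
    abort(paste0(context, ": duplicate probe_id '", dup[[1]], "'"))
  }
  for (s in samples) {
    for (ch in c("IP", "Sup")) {
      v <- tbl[[paste0(ch, "_", s)]]
      if (!is.numeric(v)) {
        abort(paste0(context, ": column ", ch, "_", s, " is not numeric"))
      }
      bad <- which(!is.finite(v) | v < 0)
      if (length(bad) > 0) {
        abort(paste0(
          context, ": negative or non-finite intensity at probe '",
          tbl$probe_id[[bad[[1]]]], "', column ", ch, "_", s
        ))
      }
    }
    fl <- tbl[[paste0("flag_", s)]]
    bad <- which(!fl %in% c("P", "M", "A"))
    if (length(bad) > 0) {
      abort(paste0(
        context, ": unknown QC flag '", fl[[bad[[1]]]], "' at probe '",
        tbl$probe_id[[bad[[1]]]], "', column flag_", s,
        " (allowed: P, M, A)"
      ))
    }
  }
  invisible(tbl)
}

#' Write an intensity table
#'
#' Writes the tab-delimited dialect read by [read_intensity_table()], with a
#' fixed column order so that serialisation is deterministic.
#'
#' @param table Intensity table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet is a CSV with columns `sample_id`, `group` and optionally
#' `replicate`, mapping each array sample to one of the three ordered
#' histology groups `OA`, `HP`, `SOMA`.
#'
#' @param path Path to a CSV sample sheet.
#' @return A tibble with columns `sample_id`, `group` (factor with levels
#'   OA, HP, SOMA) and `replicate`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("sample sheet not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("sample_id", "group")) {
    if (!col %in% names(raw)) {
      abort(paste0("sample sheet ", path, ": missing required column '", col, "'"))
    }
  }
  raw$sample_id <- as.character(raw$sample_id)
  raw$group <- as.character(raw$group)
  validate_sample_sheet(as_tibble(raw), context = path)
}

validate_sample_sheet <- function(sheet, context = "sample sheet") {
  bad <- setdiff(unique(sheet$group), merip_groups())
  if (length(bad) > 0) {
    abort(paste0(
      context, ": unknown group label '", bad[[1]], "' (allowed: ",
      paste(merip_groups(), collapse = ", "), ")"
    ))
  }
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup) > 0) {
    abort(paste0(context, ": duplicate sample_id '", dup[[1]], "'"))
  }
  sheet$group <- factor(sheet$group, levels = merip_groups())
  if (!"replicate" %in% names(sheet)) {
    sheet <- sheet |>
      group_by(.data$group) |>
      mutate(replicate = seq_len(n())) |>
      ungroup()
  }
  sheet[c("sample_id", "group", "replicate")]
}

#' Write a sample sheet
#'
#' @param sheet Sample sheet tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  out <- sheet
  out$group <- as.character(out$group)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Check that intensity-table samples match the sample sheet
#'
#' @param table Intensity table.
#' @param sheet Sample sheet.
#' @return Invisibly `TRUE`; otherwise an error naming the mismatched
#'   samples.
#' @export
check_samples <- function(table, sheet) {
  in_table <- intensity_samples(table)
  only_table <- setdiff(in_table, sheet$sample_id)
  only_sheet <- setdiff(sheet$sample_id, in_table)
  if (length(only_table) > 0 || length(only_sheet) > 0) {
    abort(paste0(
      "sample mismatch between intensity table and sample sheet: ",
      if (length(only_table) > 0) {
        paste0("only in table: ", paste(only_table, collapse = ", "), "; ")
      } else "",
      if (length(only_sheet) > 0) {
        paste0("only in sheet: ", paste(only_sheet, collapse = ", "))
      } else ""
    ))
  }
  invisible(TRUE)
}

#' Write any result table as TSV
#'
#' Deterministic tab-delimited serialisation (stable row and column order as
#' given) used for all pipeline outputs.
#'
#' @param result A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path) {
  out <- as.data.frame(result)
  for (col in names(out)) {
    if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Pivot a wide intensity table to one row per probe x sample with both
# channels and the flag; used by preprocessing and quantification.
intensity_long <- function(table) {
  samples <- intensity_samples(table)
  purrr::map_dfr(samples, function(s) {
    tibble(
      probe_id = table$probe_id,
      gene_symbol = table$gene_symbol,
      is_spikein = table$is_spikein,
      sample_id = s,
      IP = table[[paste0("IP_", s)]],
      Sup = table[[paste0("Sup_", s)]],
      flag = table[[paste0("flag_", s)]]
    )
  })
}
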