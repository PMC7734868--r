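# Input/output and assembly of the report tables (per-version category
# counts, change summaries, unchanged-percentage grid), plus the run
# config echo written alongside every output set.

#' Read structures from SMILES, CSV or SDF
#'
#' SMILES files hold one structure per line, optionally followed by a
#' tab- or space-separated id. CSV files need columns `id` (or
#' `compound_id`) and `smiles`. SDF files are read with ChemmineR and
#' converted to SMILES.
#'
#' @param path input file; format chosen by extension (`.smi`/`.txt`,
#'   `.csv`, `.sdf`).
#' @return Tibble `compound_id`, `smiles`.
#' @export
read_structures <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    id_col <- intersect(c("compound_id", "id"), names(tab))[1]
    if (is.na(id_col) || !"smiles" %in% names(tab)) {
      stop("CSV structure input needs columns id/compound_id and smiles",
           call. = FALSE)
    }
    return(tibble::tibble(compound_id = as.character(tab[[id_col]]),
                          smiles = tab$smiles))
  }
  if (ext == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    ids <- ChemmineR::sdfid(sdf)
    if (anyDuplicated(ids)) ids <- paste0("sdf_", seq_along(smi))
    return(tibble::tibble(compound_id = as.character(ids), smiles = smi))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  smiles <- vapply(parts, `[[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("smi_", i)
  }, character(1))
  tibble::tibble(compound_id = ids, smiles = smiles)
}

#' Write structures as a SMILES file
#'
#' @param structures tibble with `smiles` and `compound_id` columns.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_smiles <- function(structures, path) {
  writeLines(paste(structures$smiles, structures$compound_id, sep = "\t"),
             path)
  invisible(path)
}

#' Read a raw prediction CSV
#'
#' @param path CSV with columns `compound_id`, `vendor`, `model_type`,
#'   `version_label`, `release_year`, `raw_call`.
#' @return A tibble (unharmonized; pass to [harmonize_table()]).
#' @export
read_raw_predictions <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}

#' Write a prediction table (raw or harmonized) to CSV
#'
#' @param table data frame of predictions.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_prediction_table <- function(table, path) {
  utils::write.csv(tibble::as_tibble(table), path, row.names = FALSE)
  invisible(path)
}

#' Per-version category counts in report shape
#'
#' One row per (model, category) with one column per version label —
#' the shape of published per-version category-count tables.
#'
#' @param table a [prediction_table()].
#' @return Tibble `vendor`, `model_type`, `category`, then one column per
#'   version label (within each model) holding the counts.
#' @export
marginal_count_table <- function(table) {
  stopifnot(inherits(table, "prediction_table"))
  mv <- model_versions(table)
  long <- dplyr::bind_rows(lapply(seq_len(nrow(mv)), function(i) {
    mc <- marginal_counts(table, mv$vendor[i], mv$model_type[i],
                          mv$version_label[i])
    tibble::tibble(vendor = mv$vendor[i], model_type = mv$model_type[i],
                   version_label = mv$version_label[i],
                   category = names(mc), count = unname(mc))
  }))
  tidyr::pivot_wider(long, names_from = "version_label",
                     values_from = "count")
}

#' Write the standard change-analysis report files
#'
#' Assembles and writes: per-version marginal category counts
#' (`marginal_counts.csv`), long-form per-model transition percentages
#' over the year window (`model_changes.csv`), the consensus combination
#' summary (`consensus_changes.csv`), the unchanged-percentage grid
#' (`unchanged_report.csv`), a JSON run summary (`summary.json`) and a
#' YAML echo of the run configuration (`config_echo.yaml`).
#'
#' @param table a [prediction_table()].
#' @param dir output directory (created if needed).
#' @param from_year,to_year release-year window for change analysis.
#' @param denominator passed to [change_percentages()].
#' @return Invisibly, the named vector of files written.
#' @export
write_run_outputs <- function(table, dir, from_year, to_year,
                              denominator = "total") {
  stopifnot(inherits(table, "prediction_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()

  marg <- marginal_count_table(table)
  files["marginals"] <- file.path(dir, "marginal_counts.csv")
  utils::write.csv(marg, files["marginals"], row.names = FALSE)

  mv <- model_versions(table)
  models <- unique(mv[c("vendor", "model_type")])
  model_changes <- dplyr::bind_rows(lapply(seq_len(nrow(models)), function(i) {
    w <- version_window(mv[mv$vendor == models$vendor[i] &
                             mv$model_type == models$model_type[i], ],
                        from_year, to_year)
    if (is.null(w)) return(NULL)
    tm <- transition_matrix(table, models$vendor[i], models$model_type[i],
                            w$from, w$to)
    cs <- change_percentages(tm, denominator = denominator)
    cs$vendor <- models$vendor[i]
    cs$model_type <- models$model_type[i]
    cs$from_version <- w$from
    cs$to_version <- w$to
    tibble::as_tibble(cs)
  }))
  files["model_changes"] <- file.path(dir, "model_changes.csv")
  utils::write.csv(model_changes, files["model_changes"], row.names = FALSE)

  grid <- combination_grid(table, from_year, to_year)
  cons <- summarize_combination_changes(table, grid, from_year, to_year,
                                        denominator = denominator)
  files["consensus_changes"] <- file.path(dir, "consensus_changes.csv")
  utils::write.csv(cons, files["consensus_changes"], row.names = FALSE)

  unch <- unchanged_report(table, grid, from_year, to_year)
  files["unchanged"] <- file.path(dir, "unchanged_report.csv")
  utils::write.csv(unch$per_combination, files["unchanged"],
                   row.names = FALSE)

  cc <- conservation_check(table)
  summary <- list(
    n_compounds = length(unique(table$compound_id)),
    n_model_versions = nrow(mv),
    n_combinations = nrow(grid),
    mean_unchanged_percent = unch$mean_unchanged,
    conservation_pass = isTRUE(attr(cc, "pass")),
    from_year = from_year, to_year = to_year,
    denominator = denominator)
  files["summary"] <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, files["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  files["config"] <- file.path(dir, "config_echo.yaml")
  yaml::write_yaml(list(from_year = from_year, to_year = to_year,
                        denominator = denominator,
                        written = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                   files["config"])
  invisible(files)
}
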