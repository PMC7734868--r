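# The prediction table: a complete matrix of harmonized calls over
# (compound x model version), kept in long (tidy) form.

MODEL_TYPES <- c("statistical", "rule_based")

#' Construct and validate a prediction table
#'
#' A prediction table is a long-form tibble with one row per (compound,
#' model version) holding the harmonized `call`. Validation enforces a
#' complete matrix — every compound has exactly one call for every listed
#' model version — plus the closed call vocabulary, known model types, and
#' a plausible release-year range.
#'
#' @param x data frame with columns `compound_id`, `vendor`, `model_type`,
#'   `version_label`, `release_year`, `call` (extra columns are kept).
#' @return `x` as a tibble with class `prediction_table`.
#' @export
prediction_table <- function(x) {
  req <- c("compound_id", "vendor", "model_type", "version_label",
           "release_year", "call")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("prediction table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  x$call <- as_call(x$call)
  bad_type <- setdiff(unique(x$model_type), MODEL_TYPES)
  if (length(bad_type) > 0) {
    stop("unknown model_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$release_year < 1990 | x$release_year > 2100)) {
    stop("release_year outside plausible range 1990-2100", call. = FALSE)
  }
  mv_key <- paste(x$vendor, x$model_type, x$version_label, sep = "\r")
  cell_key <- paste(x$compound_id, mv_key, sep = "\r")
  if (anyDuplicated(cell_key)) {
    d <- which(duplicated(cell_key))[1]
    stop("duplicate cell: compound ", x$compound_id[d], ", model ",
         x$vendor[d], "/", x$model_type[d], "/", x$version_label[d],
         " (row ", d, ")", call. = FALSE)
  }
  # version labels must map to a single release year
  vy <- unique(x[c("vendor", "model_type", "version_label", "release_year")])
  if (anyDuplicated(vy[c("vendor", "model_type", "version_label")])) {
    stop("a model version is listed with two release years", call. = FALSE)
  }
  n_versions <- nrow(vy)
  counts <- table(x$compound_id)
  if (any(counts != n_versions)) {
    bad <- names(counts)[counts != n_versions][1]
    stop("incomplete matrix: compound ", bad, " has ", counts[[bad]],
         " cells, expected ", n_versions, call. = FALSE)
  }
  class(x) <- c("prediction_table", class(x))
  x
}

#' @export
print.prediction_table <- function(x, ...) {
  cat("<prediction_table> ", length(unique(x$compound_id)), " compounds x ",
      nrow(model_versions(x)), " model versions\n", sep = "")
  NextMethod()
}

#' List the model versions in a prediction table
#'
#' @param table a [prediction_table()].
#' @return Tibble `vendor`, `model_type`, `version_label`, `release_year`,
#'   ordered by model identity then release year then version label.
#' @export
model_versions <- function(table) {
  vy <- unique(tibble::as_tibble(table)[c("vendor", "model_type",
                                          "version_label", "release_year")])
  vy[order(vy$vendor, vy$model_type, vy$release_year, vy$version_label), ]
}

# Calls of one model version, ordered by compound id.
version_calls <- function(table, vendor, model_type, version_label) {
  sel <- table$vendor == vendor & table$model_type == model_type &
    table$version_label == version_label
  if (!any(sel)) {
    stop("model version not found: ", vendor, "/", model_type, "/",
         version_label, call. = FALSE)
  }
  sub <- table[sel, ]
  sub$call[order(sub$compound_id)]
}
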