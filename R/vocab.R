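# Vocabulary harmonization: vendor/model-specific prediction terms to the
# common four-category scale.

norm_term <- function(x) tolower(trimws(x))

#' Load a vocabulary map
#'
#' Reads a YAML vocabulary config mapping each (vendor, model type, raw
#' output term) to one of the four common call categories. The shipped
#' default covers the three vendors' statistical and rule-based systems,
#' including the rule-based special cases: alerting structures with
#' reasoning of equivocal or higher map to `POSITIVE`, negatives with
#' misclassified features to `NEGATIVE`, and negatives with unclassified
#' features to `OOD`. A model entry may declare `forbidden_calls` —
#' categories that system cannot emit (the default forbids `EQUIVOCAL` for
#' the Lhasa rule-based system).
#'
#' @param path YAML config path; `NULL` loads the shipped default.
#' @return A `vocab_map` object: list with `entries` (tibble `vendor`,
#'   `model_type`, `raw_term`, `call`), `forbidden` (tibble `vendor`,
#'   `model_type`, `call`) and `normalize` (logical).
#' @export
load_vocab_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocab_default.yaml",
                        package = "qsardrift")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$vendors)) stop("vocabulary config has no 'vendors' key",
                                 call. = FALSE)
  normalize <- isTRUE(cfg$normalize)
  entries <- dplyr::bind_rows(lapply(cfg$vendors, function(v) {
    stopifnot(!is.null(v$vendor), !is.null(v$model_type), !is.null(v$terms))
    tibble::tibble(vendor = v$vendor, model_type = v$model_type,
                   raw_term = names(v$terms),
                   call = unlist(v$terms, use.names = FALSE))
  }))
  forbidden <- dplyr::bind_rows(lapply(cfg$vendors, function(v) {
    if (is.null(v$forbidden_calls)) return(NULL)
    tibble::tibble(vendor = v$vendor, model_type = v$model_type,
                   call = unlist(v$forbidden_calls))
  }))
  if (nrow(forbidden) == 0) {
    forbidden <- tibble::tibble(vendor = character(),
                                model_type = character(), call = character())
  }
  entries$call <- as_call(entries$call)
  forbidden$call <- as_call(forbidden$call)
  key <- paste(entries$vendor, entries$model_type,
               if (normalize) norm_term(entries$raw_term) else
                 entries$raw_term, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- entries[duplicated(key), c("vendor", "model_type", "raw_term")]
    stop("duplicate vocabulary keys: ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = "; "),
         call. = FALSE)
  }
  viol <- dplyr::inner_join(entries, forbidden,
                            by = c("vendor", "model_type", "call"))
  if (nrow(viol) > 0) {
    stop("vocabulary maps term(s) to a call the model cannot emit: ",
         paste(viol$raw_term, collapse = ", "), call. = FALSE)
  }
  structure(list(entries = entries, forbidden = forbidden,
                 normalize = normalize),
            class = "vocab_map")
}

#' @export
print.vocab_map <- function(x, ...) {
  cat("<vocab_map> ", nrow(x$entries), " terms over ",
      nrow(unique(x$entries[c("vendor", "model_type")])), " model identities\n",
      sep = "")
  invisible(x)
}

#' Harmonize raw prediction terms to common calls
#'
#' Exact lookup (case-insensitive after trimming when the map was loaded
#' with `normalize: true`) of vendor raw terms in the vocabulary map.
#'
#' @param raw_term character vector of raw output terms.
#' @param vendor,model_type character vectors (recycled if length one)
#'   identifying the emitting model.
#' @param map a [load_vocab_map()] result.
#' @return Character vector of calls (`POSITIVE`, `NEGATIVE`, `EQUIVOCAL`,
#'   `OOD`).
#' @export
harmonize_call <- function(raw_term, vendor, model_type,
                           map = load_vocab_map()) {
  stopifnot(inherits(map, "vocab_map"))
  n <- length(raw_term)
  vendor <- rep_len(vendor, n)
  model_type <- rep_len(model_type, n)
  term <- if (map$normalize) norm_term(raw_term) else raw_term
  map_term <- if (map$normalize) norm_term(map$entries$raw_term) else
    map$entries$raw_term
  idx <- match(paste(vendor, model_type, term, sep = "\r"),
               paste(map$entries$vendor, map$entries$model_type, map_term,
                     sep = "\r"))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("unmapped prediction term '", raw_term[miss], "' for model ",
         vendor[miss], "/", model_type[miss], call. = FALSE)
  }
  map$entries$call[idx]
}

#' Harmonize a raw prediction table
#'
#' Maps every row's `raw_call` through the vocabulary map and validates the
#' result as a complete prediction matrix: every (compound, model version)
#' pair present exactly once.
#'
#' @param raw data frame with columns `compound_id`, `vendor`,
#'   `model_type`, `version_label`, `release_year`, `raw_call`.
#' @param map a [load_vocab_map()] result.
#' @return A [prediction_table()] with an added `call` column.
#' @export
harmonize_table <- function(raw, map = load_vocab_map()) {
  req <- c("compound_id", "vendor", "model_type", "version_label",
           "release_year", "raw_call")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("raw prediction table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(raw[req])
  out$call <- harmonize_call(out$raw_call, out$vendor, out$model_type, map)
  prediction_table(out)
}
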