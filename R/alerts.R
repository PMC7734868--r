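# Structural-alert (toxicophore) profiling over SMARTS patterns.

#' Read a SMARTS alert table
#'
#' Tab-separated file with header columns `name` and `smarts`. The package
#' ships a generic bacterial-mutagenicity alert set (aromatic nitro,
#' aromatic amine, N-nitroso, epoxide, acyl halide, aldehyde, ...) at
#' `system.file("extdata", "alerts_mutagenicity.tsv", package = "qsardrift")`;
#' it is a generic public set, not any vendor's proprietary alert
#' definitions.
#'
#' @param path file path; default loads the shipped set.
#' @return Named character vector of SMARTS (names are alert names).
#' @export
read_smarts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "alerts_mutagenicity.tsv",
                        package = "qsardrift")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "smarts") %in% names(tab)))
  if (anyDuplicated(tab$name)) {
    stop("duplicate alert names in ", path, call. = FALSE)
  }
  stats::setNames(tab$smarts, tab$name)
}

count_alert_matches <- function(smiles, smarts_vec) {
  mols <- ChemmineR::smiles2sdf(stats::setNames(
    smiles, paste0("m", seq_along(smiles))))
  vapply(smarts_vec, function(pat) {
    hits <- tryCatch(ChemmineR::smartsSearchOB(mols, pat),
                     error = function(e) {
                       stop("invalid SMARTS pattern: ", pat, call. = FALSE)
                     })
    sum(hits > 0)
  }, numeric(1))
}

#' Profile structural-alert frequencies over a compound set
#'
#' Counts, for each named SMARTS alert, how many compounds match it at
#' least once (a compound counts once per alert even with multiple
#' matches), then bins all alerts outside the `top_k` most frequent into an
#' `"other"` category. Ties at rank `top_k` are broken by alert name order.
#'
#' @param records compound record tibble (all `KEPT`).
#' @param alerts named character vector of SMARTS patterns.
#' @param top_k number of named alerts to keep before binning; default 6.
#' @return An object of class `alert_profile`: list with `counts` (tibble
#'   `alert`, `count`, sorted), `binned` (top-k alerts plus `other`),
#'   `total_compounds` and `top_k`.
#' @export
profile_alerts <- function(records, alerts, top_k = 6L) {
  records <- kept_records(records, "records")
  stopifnot(top_k >= 0)
  if (length(alerts) == 0) {
    prof <- tibble::tibble(alert = character(), count = integer())
    return(structure(list(counts = prof,
                          binned = tibble::tibble(alert = "other", count = 0L),
                          total_compounds = nrow(records),
                          top_k = as.integer(top_k)),
                     class = "alert_profile"))
  }
  if (is.null(names(alerts)) || any(!nzchar(names(alerts)))) {
    stop("alerts must be a named character vector of SMARTS", call. = FALSE)
  }
  counts <- count_alert_matches(records$smiles_std, alerts)
  tab <- tibble::tibble(alert = names(alerts), count = as.integer(counts))
  tab <- tab[order(-tab$count, tab$alert), ]
  k <- min(top_k, nrow(tab))
  top <- utils::head(tab, k)
  other <- sum(tab$count) - sum(top$count)
  binned <- rbind(top, tibble::tibble(alert = "other",
                                      count = as.integer(other)))
  structure(list(counts = tab, binned = binned,
                 total_compounds = nrow(records),
                 top_k = as.integer(top_k)),
            class = "alert_profile")
}

#' @export
print.alert_profile <- function(x, ...) {
  cat("<alert_profile> ", nrow(x$counts), " alerts over ",
      x$total_compounds, " compounds (top_k = ", x$top_k, ")\n", sep = "")
  print(x$binned)
  invisible(x)
}

#' Write an alert profile to CSV
#'
#' @param profile an `alert_profile`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_alert_profile <- function(profile, path) {
  stopifnot(inherits(profile, "alert_profile"))
  out <- profile$binned
  out$fraction <- ifelse(profile$total_compounds > 0,
                         out$count / profile$total_compounds, NA_real_)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
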