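# Version-to-version change analysis: transition matrices, change
# percentages, marginal counts, the stat x rule combination grid, and
# conservation checks.

new_transition_matrix <- function(counts, n_total, from_label, to_label,
                                  model = NULL) {
  structure(counts, n_total = n_total, from_label = from_label,
            to_label = to_label, model = model,
            class = c("transition_matrix", "matrix"))
}

transition_counts <- function(from_calls, to_calls) {
  stopifnot(length(from_calls) == length(to_calls))
  as.matrix(table(from = call_factor(from_calls),
                  to = call_factor(to_calls)))
}

#' Transition matrix between two versions of one model
#'
#' Cross-tabulates per-compound calls of one model at two versions:
#' `counts[f, t]` is the number of compounds called `f` at `from_version`
#' and `t` at `to_version`. The trace is the unchanged count.
#'
#' @param table a [prediction_table()].
#' @param vendor,model_type the model identity.
#' @param from_version,to_version version labels, both present in `table`.
#' @return A 4x4 `transition_matrix` (rows = from, columns = to) with
#'   attributes `n_total`, `from_label`, `to_label`, `model`.
#' @export
transition_matrix <- function(table, vendor, model_type,
                              from_version, to_version) {
  stopifnot(inherits(table, "prediction_table"))
  f <- version_calls(table, vendor, model_type, from_version)
  t_ <- version_calls(table, vendor, model_type, to_version)
  new_transition_matrix(transition_counts(f, t_), n_total = length(f),
                        from_label = from_version, to_label = to_version,
                        model = paste(vendor, model_type, sep = "/"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> ", attr(x, "model"), ": ",
      attr(x, "from_label"), " -> ", attr(x, "to_label"),
      " (n = ", attr(x, "n_total"), ")\n", sep = "")
  print(unclass(x))
  invisible(x)
}

# Pick the earliest and latest version of a model within a year window.
version_window <- function(mv, from_year = NULL, to_year = NULL) {
  if (!is.null(from_year)) mv <- mv[mv$release_year >= from_year, ]
  if (!is.null(to_year)) mv <- mv[mv$release_year <= to_year, ]
  if (nrow(mv) == 0) return(NULL)
  mv <- mv[order(mv$release_year, mv$version_label), ]
  list(from = mv$version_label[1], to = mv$version_label[nrow(mv)])
}

#' Consensus transition matrix for a model combination
#'
#' Computes the consensus call per compound at two time points (for each
#' model, the earliest version released in `[from_year, to_year]` versus
#' the latest) and cross-tabulates the transitions.
#'
#' @param table a [prediction_table()].
#' @param stat_vendor,rule_vendor vendors of the statistical and
#'   rule-based member.
#' @param from_year,to_year release-year window (e.g. 2014 and 2018).
#' @return A `transition_matrix`; attribute `model` records the
#'   combination and its intra/inter label.
#' @export
consensus_transition_matrix <- function(table, stat_vendor, rule_vendor,
                                        from_year, to_year) {
  stopifnot(inherits(table, "prediction_table"))
  sw <- version_window(resolve_model(table, stat_vendor, "statistical"),
                       from_year, to_year)
  rw <- version_window(resolve_model(table, rule_vendor, "rule_based"),
                       from_year, to_year)
  if (is.null(sw) || is.null(rw)) {
    stop("no model version released in [", from_year, ", ", to_year,
         "] for one of the combination members", call. = FALSE)
  }
  c_from <- consensus_table(table, stat_vendor, sw$from, rule_vendor,
                            rw$from)
  c_to <- consensus_table(table, stat_vendor, sw$to, rule_vendor, rw$to)
  label <- if (stat_vendor == rule_vendor) "intra" else "inter"
  new_transition_matrix(
    transition_counts(c_from$call, c_to$call),
    n_total = nrow(c_from),
    from_label = paste0(sw$from, "+", rw$from),
    to_label = paste0(sw$to, "+", rw$to),
    model = paste0(stat_vendor, " statistical x ", rule_vendor,
                   " rule_based (", label, ")"))
}

#' Change percentages from a transition matrix
#'
#' With the `"total"` denominator every cell is divided by the compound
#' total (the convention behind statements like "x% of the compounds
#' changed from negative to positive"); with `"from_category"` each row is
#' divided by its own sum, giving conditional rates, and rows with zero sum
#' are reported as `NaN` (undefined), not 0.
#'
#' @param matrix a `transition_matrix`.
#' @param denominator `"total"` or `"from_category"`.
#' @return A `change_summary`: tibble `from`, `to`, `count`, `percent`,
#'   with attributes `unchanged_percent`, `denominator` and `n_total`.
#' @export
change_percentages <- function(matrix,
                               denominator = c("total", "from_category")) {
  stopifnot(inherits(matrix, "transition_matrix"))
  denominator <- match.arg(denominator)
  n_total <- attr(matrix, "n_total")
  stopifnot(n_total > 0)
  m <- unclass(matrix)
  pct <- if (denominator == "total") {
    100 * m / n_total
  } else {
    rs <- rowSums(m)
    sweep(m, 1, rs, "/") * 100  # zero rows -> NaN
  }
  long <- tibble::tibble(
    from = rep(rownames(m), times = ncol(m)),
    to = rep(colnames(m), each = nrow(m)),
    count = as.vector(m),
    percent = as.vector(pct))
  structure(long,
            unchanged_percent = 100 * sum(diag(m)) / n_total,
            denominator = denominator,
            n_total = n_total,
            class = c("change_summary", class(long)))
}

#' Marginal category counts for one model version
#'
#' @param table a [prediction_table()].
#' @param vendor,model_type,version_label the model version.
#' @return Named integer vector over the four call categories, summing to
#'   the compound count.
#' @export
marginal_counts <- function(table, vendor, model_type, version_label) {
  stopifnot(inherits(table, "prediction_table"))
  calls <- version_calls(table, vendor, model_type, version_label)
  out <- base::table(call_factor(calls))
  stats::setNames(as.integer(out), names(out))
}

#' All statistical x rule-based model combinations
#'
#' Enumerates the full Cartesian product of statistical and rule-based
#' model identities present in the table, labelled `"intra"` when both
#' come from one vendor and `"inter"` otherwise. When a year window is
#' given, only models with at least one version released in the window are
#' combined, and the initial/contemporary version labels within the window
#' are attached.
#'
#' @param table a [prediction_table()].
#' @param from_year,to_year optional release-year window.
#' @return Tibble `stat_vendor`, `rule_vendor`, `label`, `stat_from`,
#'   `stat_to`, `rule_from`, `rule_to`.
#' @export
combination_grid <- function(table, from_year = NULL, to_year = NULL) {
  stopifnot(inherits(table, "prediction_table"))
  mv <- model_versions(table)
  models <- unique(mv[c("vendor", "model_type")])
  stats_ <- models$vendor[models$model_type == "statistical"]
  rules <- models$vendor[models$model_type == "rule_based"]
  if (length(stats_) == 0 || length(rules) == 0) {
    stop("need at least one statistical and one rule-based model",
         call. = FALSE)
  }
  grid <- expand.grid(stat_vendor = stats_, rule_vendor = rules,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("stat_vendor",
                                                  "rule_vendor")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sv <- grid$stat_vendor[i]; rv <- grid$rule_vendor[i]
    sw <- version_window(mv[mv$vendor == sv &
                              mv$model_type == "statistical", ],
                         from_year, to_year)
    rw <- version_window(mv[mv$vendor == rv &
                              mv$model_type == "rule_based", ],
                         from_year, to_year)
    if (is.null(sw) || is.null(rw)) return(NULL)
    tibble::tibble(stat_vendor = sv, rule_vendor = rv,
                   label = if (sv == rv) "intra" else "inter",
                   stat_from = sw$from, stat_to = sw$to,
                   rule_from = rw$from, rule_to = rw$to)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$stat_vendor, out$rule_vendor), ]
}

#' Unchanged-prediction report over all model combinations
#'
#' For every statistical x rule-based combination, the percentage of
#' compounds whose consensus call is identical at the start and end of the
#' year window, plus the arithmetic mean over combinations.
#'
#' @param table a [prediction_table()].
#' @param grid combination grid from [combination_grid()]; computed from
#'   `table` when `NULL`.
#' @param from_year,to_year release-year window.
#' @return List with `per_combination` (the grid plus `unchanged_percent`)
#'   and `mean_unchanged`.
#' @export
unchanged_report <- function(table, grid = NULL, from_year, to_year) {
  if (is.null(grid)) grid <- combination_grid(table, from_year, to_year)
  stopifnot(nrow(grid) > 0)
  pct <- vapply(seq_len(nrow(grid)), function(i) {
    tm <- consensus_transition_matrix(table, grid$stat_vendor[i],
                                      grid$rule_vendor[i],
                                      from_year, to_year)
    100 * sum(diag(unclass(tm))) / attr(tm, "n_total")
  }, numeric(1))
  per <- grid
  per$unchanged_percent <- pct
  list(per_combination = per, mean_unchanged = mean(pct))
}

#' Mean consensus change percentages across model combinations
#'
#' Computes, for every (from, to) category pair, the consensus change
#' percentage of each statistical x rule-based combination over the year
#' window and summarizes across combinations with the arithmetic mean
#' (plus range), the summary used to report average inter-/intra-vendor
#' consensus changes.
#'
#' @inheritParams unchanged_report
#' @param denominator passed to [change_percentages()].
#' @return Tibble `from`, `to`, `mean_percent`, `min_percent`,
#'   `max_percent`, `n_combinations`.
#' @export
summarize_combination_changes <- function(table, grid = NULL, from_year,
                                          to_year,
                                          denominator = "total") {
  if (is.null(grid)) grid <- combination_grid(table, from_year, to_year)
  stopifnot(nrow(grid) > 0)
  per <- lapply(seq_len(nrow(grid)), function(i) {
    tm <- consensus_transition_matrix(table, grid$stat_vendor[i],
                                      grid$rule_vendor[i],
                                      from_year, to_year)
    cs <- change_percentages(tm, denominator = denominator)
    cs$combination <- paste0(grid$stat_vendor[i], "x", grid$rule_vendor[i])
    cs
  })
  all <- dplyr::bind_rows(per)
  dplyr::summarise(dplyr::group_by(all, .data$from, .data$to),
                   mean_percent = mean(.data$percent),
                   min_percent = min(.data$percent),
                   max_percent = max(.data$percent),
                   n_combinations = dplyr::n(),
                   .groups = "drop")
}

#' Conservation check on category counts
#'
#' Verifies that, for every model version, the four category counts sum to
#' the compound total. Accepts either a [prediction_table()] (the total is
#' the table's compound count) or an external counts table — e.g. published
#' per-version category counts entered as a fixture — with columns
#' `vendor`, `model_type`, `version_label`, `n_positive`, `n_negative`,
#' `n_equivocal`, `n_ood` and `expected_total`. Violations are reported,
#' never corrected.
#'
#' @param x a prediction table or an external counts data frame (see
#'   [read_category_counts()]).
#' @return Tibble `vendor`, `model_type`, `version_label`, `total`,
#'   `expected`, `pass`; attribute `pass` is `TRUE` when every row passes.
#' @export
conservation_check <- function(x) {
  if (inherits(x, "prediction_table")) {
    mv <- model_versions(x)
    n <- length(unique(x$compound_id))
    total <- vapply(seq_len(nrow(mv)), function(i) {
      sum(marginal_counts(x, mv$vendor[i], mv$model_type[i],
                          mv$version_label[i]))
    }, numeric(1))
    out <- tibble::tibble(vendor = mv$vendor, model_type = mv$model_type,
                          version_label = mv$version_label,
                          total = as.integer(total),
                          expected = as.integer(n))
  } else {
    req <- c("vendor", "model_type", "version_label", "n_positive",
             "n_negative", "n_equivocal", "n_ood", "expected_total")
    missing_cols <- setdiff(req, names(x))
    if (length(missing_cols) > 0) {
      stop("counts table lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    out <- tibble::tibble(
      vendor = x$vendor, model_type = x$model_type,
      version_label = x$version_label,
      total = as.integer(x$n_positive + x$n_negative + x$n_equivocal +
                           x$n_ood),
      expected = as.integer(x$expected_total))
  }
  out$pass <- out$total == out$expected
  structure(out, pass = all(out$pass))
}

#' Read an external category-counts fixture
#'
#' CSV with one row per model version and columns `vendor`, `model_type`,
#' `version_label`, `release_year`, `n_positive`, `n_negative`,
#' `n_equivocal`, `n_ood`, `expected_total`. The shipped default contains
#' the published per-version category counts of the three vendors'
#' statistical, rule-based and consensus outputs over a 3367-compound
#' impurity-like dataset.
#'
#' @param path CSV path; `NULL` loads the shipped fixture.
#' @return A tibble.
#' @export
read_category_counts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "published_category_counts.csv",
                        package = "qsardrift")
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
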