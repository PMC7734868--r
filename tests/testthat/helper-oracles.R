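# Independent oracles and small fixture builders used across the suite.

CALLS <- c("POSITIVE", "NEGATIVE", "EQUIVOCAL", "OOD")

# Severity-max closed form for the consensus rules, implemented
# independently of the package's rule list.
oracle_consensus <- function(a, b) {
  sev <- c(NEGATIVE = 1, OOD = 2, EQUIVOCAL = 3, POSITIVE = 4)
  names(sev)[pmax(sev[a], sev[b])]
}

# Brute-force per-compound recount of a transition matrix.
oracle_transition <- function(from_calls, to_calls) {
  m <- matrix(0L, 4, 4, dimnames = list(CALLS, CALLS))
  for (i in seq_along(from_calls)) {
    m[from_calls[i], to_calls[i]] <- m[from_calls[i], to_calls[i]] + 1L
  }
  m
}

# Union-find connected components over a thresholded similarity matrix.
oracle_components <- function(sim, threshold) {
  n <- nrow(sim)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sim[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- table(roots)
  list(n_components = length(sizes), n_singletons = sum(sizes == 1))
}

# Build a minimal single-model prediction table from per-version call
# vectors (list of character vectors, one per version).
toy_table <- function(calls_by_version, vendor = "V",
                      model_type = "statistical",
                      years = NULL) {
  n <- length(calls_by_version[[1]])
  if (is.null(years)) years <- 2013L + seq_along(calls_by_version)
  rows <- lapply(seq_along(calls_by_version), function(v) {
    tibble::tibble(compound_id = sprintf("c%03d", seq_len(n)),
                   vendor = vendor, model_type = model_type,
                   version_label = paste0("v", v),
                   release_year = years[v],
                   call = calls_by_version[[v]])
  })
  prediction_table(dplyr::bind_rows(rows))
}

# Random complete prediction table for oracle-equivalence testing:
# one model, n compounds, k versions.
random_table <- function(n, k, vendor = "V", model_type = "statistical") {
  calls <- lapply(seq_len(k), function(i) sample(CALLS, n, replace = TRUE))
  toy_table(calls, vendor = vendor, model_type = model_type)
}

# Calls of one version of the single-model toy/random tables, ordered by
# compound id (independent of the package's version_calls helper).
version_calls_for_test <- function(tab, version) {
  sub <- tab[tab$version_label == version, ]
  sub$call[order(sub$compound_id)]
}

# A two-model (stat + rule) table built from explicit call vectors at two
# time points.
pair_table <- function(stat_from, stat_to, rule_from, rule_to,
                       vendor = "V") {
  n <- length(stat_from)
  ids <- sprintf("c%03d", seq_len(n))
  mk <- function(mt, ver, yr, calls) {
    tibble::tibble(compound_id = ids, vendor = vendor, model_type = mt,
                   version_label = ver, release_year = yr, call = calls)
  }
  prediction_table(dplyr::bind_rows(
    mk("statistical", "s1", 2014L, stat_from),
    mk("statistical", "s2", 2018L, stat_to),
    mk("rule_based", "r1", 2014L, rule_from),
    mk("rule_based", "r2", 2018L, rule_to)))
}
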