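test_that("the default map encodes the rule-based special cases", {
  map <- load_vocab_map()
  expect_equal(harmonize_call("Negative with unclassified features",
                              "Lhasa", "rule_based", map), "OOD")
  expect_equal(harmonize_call("Negative with misclassified features",
                              "Lhasa", "rule_based", map), "NEGATIVE")
  expect_equal(harmonize_call("Alerting structure (equivocal)",
                              "Lhasa", "rule_based", map), "POSITIVE")
  expect_equal(harmonize_call("Indeterminate", "Leadscope", "statistical",
                              map), "EQUIVOCAL")
  expect_equal(harmonize_call("Inconclusive", "MultiCASE", "rule_based",
                              map), "EQUIVOCAL")
})

test_that("lookup normalizes case and whitespace, and rejects unmapped terms", {
  map <- load_vocab_map()
  expect_equal(harmonize_call("  NEGATIVE ", "Leadscope", "statistical",
                              map), "NEGATIVE")
  expect_error(harmonize_call("Plausible alert", "Lhasa", "rule_based", map),
               "Plausible alert")
  # every default entry round-trips to its own call
  e <- map$entries
  expect_identical(harmonize_call(e$raw_term, e$vendor, e$model_type, map),
                   e$call)
})

test_that("configs with duplicate keys or forbidden calls are rejected", {
  dup <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("normalize: true", "vendors:",
               "- vendor: A", "  model_type: statistical", "  terms:",
               "    Pos: POSITIVE", "    ' pos ': NEGATIVE"), dup)
  expect_error(load_vocab_map(dup), "duplicate")
  forb <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("normalize: true", "vendors:",
               "- vendor: A", "  model_type: rule_based",
               "  forbidden_calls: [EQUIVOCAL]", "  terms:",
               "    Maybe: EQUIVOCAL"), forb)
  expect_error(load_vocab_map(forb), "cannot emit")
})

test_that("harmonize_table builds a complete matrix and flags defects", {
  raw <- expand.grid(compound_id = c("c1", "c2"),
                     version_label = c("v1", "v2"),
                     stringsAsFactors = FALSE)
  raw$vendor <- "Leadscope"
  raw$model_type <- "statistical"
  raw$release_year <- ifelse(raw$version_label == "v1", 2014L, 2018L)
  raw$raw_call <- c("Positive", "Negative", "Indeterminate",
                    "Not in domain")
  tab <- harmonize_table(raw)
  expect_s3_class(tab, "prediction_table")
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$call, c("POSITIVE", "NEGATIVE", "EQUIVOCAL", "OOD"))
  # duplicate cell
  expect_error(harmonize_table(rbind(raw, raw[1, ])), "duplicate cell")
  # missing cell
  expect_error(harmonize_table(raw[-1, ]), "incomplete matrix")
})

test_that("a table covering all six model identities round-trips as expected", {
  map <- load_vocab_map()
  idents <- unique(map$entries[c("vendor", "model_type")])
  expect_equal(nrow(idents), 6)
  raws <- c(POSITIVE = NA, NEGATIVE = NA, EQUIVOCAL = NA, OOD = NA)
  rows <- lapply(seq_len(nrow(idents)), function(i) {
    v <- idents$vendor[i]; mt <- idents$model_type[i]
    sub <- map$entries[map$entries$vendor == v &
                         map$entries$model_type == mt, ]
    # one compound per call category the model can emit; pad with NEGATIVE
    calls <- c("POSITIVE", "NEGATIVE",
               if (any(sub$call == "EQUIVOCAL")) "EQUIVOCAL" else "NEGATIVE",
               "OOD")
    terms <- vapply(calls, function(cl) sub$raw_term[sub$call == cl][1],
                    character(1))
    tibble::tibble(compound_id = paste0("c", 1:4), vendor = v,
                   model_type = mt, version_label = "v1",
                   release_year = 2014L, raw_call = unname(terms),
                   expected = calls)
  })
  raw <- dplyr::bind_rows(rows)
  tab <- harmonize_table(raw[setdiff(names(raw), "expected")])
  expect_identical(tab$call, raw$expected)
})

test_that("category counts are invariant under row permutation", {
  spec <- default_history_spec(n_compounds = 50, seed = 2)
  raw <- simulate_history(spec)[, 1:6]
  t1 <- harmonize_table(raw)
  t2 <- harmonize_table(raw[sample(nrow(raw)), ])
  for (ver in list(c("statistical", "S1"), c("rule_based", "R1"))) {
    expect_equal(marginal_counts(t1, "Leadscope", ver[1], ver[2]),
                 marginal_counts(t2, "Leadscope", ver[1], ver[2]))
  }
})
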