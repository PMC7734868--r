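test_that("simulation is reproducible and validates its spec", {
  s1 <- simulate_history(default_history_spec(n_compounds = 40, seed = 5))
  s2 <- simulate_history(default_history_spec(n_compounds = 40, seed = 5))
  expect_identical(s1, s2)
  s3 <- simulate_history(default_history_spec(n_compounds = 40, seed = 6))
  expect_false(identical(s1, s3))
  bad_init <- c(POSITIVE = 0.5, NEGATIVE = 0.6, EQUIVOCAL = 0, OOD = 0)
  expect_error(history_model("A", "statistical", "v1", 2014L, bad_init,
                             list()), "probability")
  k <- matrix(0.25, 4, 4, dimnames = list(CALLS, CALLS))
  k[1, 1] <- 0.5  # row no longer sums to 1
  expect_error(history_model("A", "statistical", c("v1", "v2"),
                             c(2014L, 2018L),
                             c(POSITIVE = 1, NEGATIVE = 0, EQUIVOCAL = 0,
                               OOD = 0), k), "sum to 1")
})

test_that("identity kernels keep every version column identical", {
  ident <- diag(4)
  dimnames(ident) <- list(CALLS, CALLS)
  init <- c(POSITIVE = 0.3, NEGATIVE = 0.5, EQUIVOCAL = 0.1, OOD = 0.1)
  models <- list(
    history_model("Leadscope", "statistical", c("S1", "S2"),
                  c(2014L, 2018L), init, ident),
    history_model("Leadscope", "rule_based", c("R1", "R2"),
                  c(2014L, 2018L), init, ident))
  raw <- simulate_history(history_spec(60, models, seed = 3))
  tab <- harmonize_table(raw[, 1:6])
  for (mv in list(c("statistical", "S1", "S2"),
                  c("rule_based", "R1", "R2"))) {
    tm <- transition_matrix(tab, "Leadscope", mv[1], mv[2], mv[3])
    expect_equal(sum(diag(unclass(tm))), 60)
  }
  rep_ <- unchanged_report(tab, NULL, 2014, 2018)
  expect_equal(rep_$per_combination$unchanged_percent, 100)
  expect_equal(rep_$mean_unchanged, 100)
})

test_that("simulated raw terms harmonize back to the generating calls", {
  spec <- default_history_spec(n_compounds = 80, seed = 12)
  raw <- simulate_history(spec)
  tab <- harmonize_table(raw[, 1:6])
  merged <- dplyr::left_join(
    tibble::as_tibble(tab),
    raw[c("compound_id", "vendor", "model_type", "version_label", "call")],
    by = c("compound_id", "vendor", "model_type", "version_label"),
    suffix = c("", ".gen"))
  expect_identical(merged$call, merged$call.gen)
  # the Lhasa-style rule-based model never emits EQUIVOCAL
  lh <- tab[tab$vendor == "Lhasa" & tab$model_type == "rule_based", ]
  expect_false(any(lh$call == "EQUIVOCAL"))
})

test_that("structure generation is deterministic with controllable defects", {
  g1 <- generate_structures(25, seed = 9)
  g2 <- generate_structures(25, seed = 9)
  expect_identical(g1, g2)
  clean <- standardize_structures(g1$smiles, g1$compound_id)
  expect_equal(sum(clean$status == "KEPT"), 25)
  mix <- generate_structures(40, seed = 10, defect_fraction = 0.3,
                             defect_types = "mixture")
  recs <- standardize_structures(mix$smiles, mix$compound_id)
  rejected <- recs[recs$status == "REJECTED", ]
  expect_equal(nrow(rejected), round(40 * 0.3))
  expect_true(all(rejected$reject_reason == "MIXTURE"))
})

test_that("coupling raises stat/rule agreement without breaking marginals", {
  base <- default_history_spec(n_compounds = 800, seed = 15, coupling = 0)
  tight <- default_history_spec(n_compounds = 800, seed = 15,
                                coupling = 0.9)
  agree <- function(spec) {
    raw <- simulate_history(spec)
    tab <- harmonize_table(raw[, 1:6])
    ct <- consensus_table(tab, "Leadscope", "S1", "Leadscope", "R1")
    mean((ct$stat_call == "POSITIVE") == (ct$rule_call == "POSITIVE"))
  }
  expect_gt(agree(tight), agree(base))
})
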