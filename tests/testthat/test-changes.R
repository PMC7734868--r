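test_that("transition matrices count per-compound category moves", {
  from <- c("POSITIVE", "NEGATIVE", "NEGATIVE", "EQUIVOCAL", "OOD")
  to <- c("NEGATIVE", "NEGATIVE", "POSITIVE", "EQUIVOCAL", "OOD")
  tab <- toy_table(list(from, to))
  tm <- transition_matrix(tab, "V", "statistical", "v1", "v2")
  expect_equal(tm["POSITIVE", "NEGATIVE"], 1)
  expect_equal(tm["NEGATIVE", "POSITIVE"], 1)
  expect_equal(tm["NEGATIVE", "NEGATIVE"], 1)
  expect_equal(sum(diag(unclass(tm))), 3)
  expect_equal(attr(tm, "n_total"), 5)
  # identical columns give a diagonal matrix with full trace
  same <- toy_table(list(from, from))
  tms <- transition_matrix(same, "V", "statistical", "v1", "v2")
  expect_equal(sum(diag(unclass(tms))), 5)
  expect_equal(sum(unclass(tms)) - sum(diag(unclass(tms))), 0)
  # reversing from/to transposes
  rev <- transition_matrix(tab, "V", "statistical", "v2", "v1")
  expect_equal(unclass(rev), t(unclass(tm)), ignore_attr = TRUE)
})

test_that("change percentages follow the chosen denominator", {
  from <- c("POSITIVE", "NEGATIVE", "NEGATIVE", "EQUIVOCAL", "OOD")
  to <- c("NEGATIVE", "NEGATIVE", "POSITIVE", "EQUIVOCAL", "OOD")
  tab <- toy_table(list(from, to))
  tm <- transition_matrix(tab, "V", "statistical", "v1", "v2")
  tot <- change_percentages(tm, "total")
  expect_equal(tot$percent[tot$from == "NEGATIVE" & tot$to == "POSITIVE"],
               20)
  expect_equal(attr(tot, "unchanged_percent"), 60)
  expect_equal(sum(tot$percent), 100)
  cond <- change_percentages(tm, "from_category")
  expect_equal(cond$percent[cond$from == "NEGATIVE" & cond$to == "POSITIVE"],
               50)
  # a from-category with no compounds is undefined, not zero
  no_pos <- toy_table(list(c("NEGATIVE", "OOD"), c("NEGATIVE", "OOD")))
  cp <- change_percentages(
    transition_matrix(no_pos, "V", "statistical", "v1", "v2"),
    "from_category")
  expect_true(all(is.nan(cp$percent[cp$from == "POSITIVE"])))
})

test_that("marginal counts partition the compound total", {
  tab <- toy_table(list(c("POSITIVE", "POSITIVE", "NEGATIVE", "EQUIVOCAL",
                          "OOD", "NEGATIVE")))
  mc <- marginal_counts(tab, "V", "statistical", "v1")
  expect_equal(unname(mc), c(2L, 2L, 1L, 1L))
  expect_equal(sum(mc), 6)
  expect_equal(unname(mc["OOD"]), 1L)
})

test_that("matrices and percentages match a brute-force recount on random tables", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    k <- sample(2:4, 1)
    tab <- random_table(n, k)
    vers <- paste0("v", 1:k)
    for (pair in list(c(1, k), c(1, 2))) {
      f <- version_calls_for_test(tab, vers[pair[1]])
      t_ <- version_calls_for_test(tab, vers[pair[2]])
      tm <- transition_matrix(tab, "V", "statistical", vers[pair[1]],
                              vers[pair[2]])
      expect_equal(unclass(tm), oracle_transition(f, t_),
                   ignore_attr = TRUE)
      cs <- change_percentages(tm, "total")
      expect_equal(attr(cs, "unchanged_percent"), 100 * mean(f == t_))
    }
  }
})

test_that("the combination grid enumerates stat x rule products with labels", {
  spec <- default_history_spec(n_compounds = 20, seed = 6)
  tab <- harmonize_table(simulate_history(spec)[, 1:6])
  grid <- combination_grid(tab, 2014, 2018)
  expect_equal(nrow(grid), 9)
  expect_equal(sum(grid$label == "intra"), 3)
  expect_equal(sum(grid$label == "inter"), 6)
  # single vendor with one stat and one rule model: one intra pair
  tab1 <- pair_table(c("NEGATIVE"), c("NEGATIVE"), c("NEGATIVE"),
                     c("NEGATIVE"))
  g1 <- combination_grid(tab1, 2014, 2018)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$label, "intra")
  # a vendor with only a statistical model appears only as stat member
  extra <- dplyr::bind_rows(
    tibble::as_tibble(tab1),
    tibble::tibble(compound_id = "c001", vendor = "S_only",
                   model_type = "statistical", version_label = "x1",
                   release_year = 2015L, call = "NEGATIVE"))
  g2 <- combination_grid(prediction_table(extra), 2014, 2018)
  expect_setequal(unique(g2$stat_vendor), c("V", "S_only"))
  expect_setequal(unique(g2$rule_vendor), "V")
})

test_that("consensus transitions and unchanged percentages match hand analysis", {
  # one model flips one compound NEGATIVE->POSITIVE; the partner stays
  # NEGATIVE for c1 and is already POSITIVE for c2
  tab <- pair_table(stat_from = c("NEGATIVE", "NEGATIVE", "NEGATIVE",
                                  "NEGATIVE"),
                    stat_to = c("POSITIVE", "POSITIVE", "NEGATIVE",
                                "NEGATIVE"),
                    rule_from = c("NEGATIVE", "POSITIVE", "NEGATIVE",
                                  "NEGATIVE"),
                    rule_to = c("NEGATIVE", "POSITIVE", "NEGATIVE",
                                "NEGATIVE"))
  tm <- consensus_transition_matrix(tab, "V", "V", 2014, 2018)
  expect_equal(tm["NEGATIVE", "POSITIVE"], 1)  # c1 only
  expect_equal(tm["POSITIVE", "POSITIVE"], 1)  # c2 was already positive
  expect_equal(tm["NEGATIVE", "NEGATIVE"], 2)
  rep_ <- unchanged_report(tab, NULL, 2014, 2018)
  expect_equal(rep_$per_combination$unchanged_percent, 75)
  expect_equal(rep_$mean_unchanged, 75)
  # identical model outputs at both years: diagonal, 100% unchanged
  same <- pair_table(rep("NEGATIVE", 3), rep("NEGATIVE", 3),
                     rep("OOD", 3), rep("OOD", 3))
  tms <- consensus_transition_matrix(same, "V", "V", 2014, 2018)
  expect_equal(sum(diag(unclass(tms))), 3)
  expect_equal(unchanged_report(same, NULL, 2014, 2018)$mean_unchanged, 100)
})

test_that("unchanged percentages match a brute-force per-compound comparison", {
  spec <- default_history_spec(n_compounds = 150, seed = 31)
  tab <- harmonize_table(simulate_history(spec)[, 1:6])
  grid <- combination_grid(tab, 2014, 2018)
  rep_ <- unchanged_report(tab, grid, 2014, 2018)
  for (i in seq_len(nrow(grid))) {
    cf <- consensus_table(tab, grid$stat_vendor[i], grid$stat_from[i],
                          grid$rule_vendor[i], grid$rule_from[i])
    ct <- consensus_table(tab, grid$stat_vendor[i], grid$stat_to[i],
                          grid$rule_vendor[i], grid$rule_to[i])
    expect_equal(rep_$per_combination$unchanged_percent[i],
                 100 * mean(cf$call == ct$call))
  }
  expect_equal(rep_$mean_unchanged,
               mean(rep_$per_combination$unchanged_percent))
})

test_that("conservation checks pass on well-formed tables and flag bad rows", {
  tab <- toy_table(list(sample(CALLS, 30, TRUE), sample(CALLS, 30, TRUE)))
  cc <- conservation_check(tab)
  expect_true(attr(cc, "pass"))
  counts <- tibble::tibble(vendor = "X", model_type = "statistical",
                           version_label = c("a", "b"),
                           n_positive = c(10L, 10L),
                           n_negative = c(5L, 5L),
                           n_equivocal = c(1L, 1L), n_ood = c(0L, 1L),
                           expected_total = c(16L, 16L))
  cc2 <- conservation_check(counts)
  expect_equal(cc2$pass, c(TRUE, FALSE))
  expect_false(attr(cc2, "pass"))
})
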