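std <- function(smiles, prefix = "q") {
  standardize_structures(smiles, paste0(prefix, seq_along(smiles)))
}

test_that("select_similar keeps exact matches and honors the cutoff", {
  query <- std(c("CCO", "c1ccccc1N", "CCCCCCCC"))
  ref <- std(c("CCO", "c1ccc(N)cc1C"), prefix = "r")
  sel <- select_similar(query, ref, cutoff = 0.5)
  expect_true("q1" %in% sel)   # exact copy of a reference, similarity 1
  # cutoff 1.0 with no exact octane match drops everything but ethanol
  sel1 <- select_similar(query, ref, cutoff = 1.0)
  expect_identical(sel1, "q1")
  expect_error(select_similar(query, ref[0, ], cutoff = 0.5), "empty")
})

test_that("selection equals the brute-force max-similarity filter", {
  query <- std(c("CCO", "c1ccccc1N", "CC(=O)OC"))
  ref <- std(c("OCC", "c1ccc(N)cc1"), prefix = "r")
  fq <- fragment_fingerprints(query$smiles_std, depth = 3)
  fr <- fragment_fingerprints(ref$smiles_std, depth = 3)
  best <- vapply(fq, function(a) {
    max(vapply(fr, function(b) tanimoto(a, b), numeric(1)))
  }, numeric(1))
  expect_identical(select_similar(query, ref, cutoff = 0.5, depth = 3),
                   query$compound_id[best >= 0.5])
})

test_that("selection is monotone in the cutoff", {
  gen <- generate_structures(20, seed = 8)
  ref <- generate_structures(8, seed = 80, prefix = "ref")
  q <- standardize_structures(gen$smiles, gen$compound_id)
  r <- standardize_structures(ref$smiles, ref$compound_id)
  cuts <- c(0.2, 0.4, 0.6, 0.8)
  sels <- lapply(cuts, function(ct) select_similar(q, r, cutoff = ct))
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(sels[[i + 1]] %in% sels[[i]]))
  }
})

test_that("exclusion removes structural matches regardless of id", {
  recs <- std(c("CCO", "CCN", "OCC"))
  sel <- recs$compound_id
  expect_identical(exclude_known(sel, recs, character()), sel)
  # "OCC" is ethanol: both ethanol ids must go
  out <- exclude_known(sel, recs, "OCC")
  expect_identical(out, "q2")
})

test_that("curation funnel conserves record counts", {
  gen <- generate_structures(40, seed = 13, defect_fraction = 0.3)
  recs <- standardize_structures(gen$smiles, gen$compound_id)
  by_reason <- table(recs$reject_reason[recs$status == "REJECTED"])
  expect_equal(sum(recs$status == "KEPT") + sum(by_reason), nrow(gen))
  kept <- recs[recs$status == "KEPT", ]
  ref <- generate_structures(10, seed = 77, prefix = "ref")
  refr <- standardize_structures(ref$smiles, ref$compound_id)
  sel <- select_similar(kept, refr[refr$status == "KEPT", ], cutoff = 0.3)
  expect_false(anyDuplicated(sel) > 0)
  final <- exclude_known(sel, kept, ref$smiles[1:3])
  n_excluded <- length(sel) - length(final)
  expect_gte(n_excluded, 0)
  expect_equal(length(final), length(sel) - n_excluded)
  expect_true(all(final %in% sel))
})

test_that("similarity graph matches brute-force edges and components", {
  q <- std(c("CCO", "OCC", "CCCCCCCCCC"))
  r <- std("CCO", prefix = "r")
  g <- build_similarity_graph(q, r, threshold = 0.5)
  s <- similarity_graph_summary(g)
  # three ethanol spellings form one clique, decane is a singleton
  expect_equal(s$n_components, 2)
  expect_equal(s$n_singletons, 1)
  expect_equal(s$n_edges, 3)
  expect_equal(unique(igraph::E(g)$weight), 1)

  gen <- generate_structures(25, seed = 21)
  ref <- generate_structures(10, seed = 22, prefix = "ref")
  qa <- standardize_structures(gen$smiles, gen$compound_id)
  ra <- standardize_structures(ref$smiles, ref$compound_id)
  g2 <- build_similarity_graph(qa, ra, threshold = 0.5)
  fps <- fragment_fingerprints(c(qa$smiles_std, ra$smiles_std), depth = 7)
  sim <- tanimoto_matrix(fps, fps)
  expect_equal(igraph::ecount(g2), sum(sim[upper.tri(sim)] >= 0.5))
  oc <- oracle_components(sim, 0.5)
  s2 <- similarity_graph_summary(g2)
  expect_equal(s2$n_components, oc$n_components)
  expect_equal(s2$n_singletons, oc$n_singletons)
})

test_that("graph export writes GraphML and an edge list", {
  q <- std(c("CCO", "OCC"))
  r <- std("CCN", prefix = "r")
  g <- build_similarity_graph(q, r, threshold = 0.5)
  dir <- withr::local_tempdir()
  paths <- write_similarity_graph(g, dir)
  expect_true(all(file.exists(paths)))
  edges <- utils::read.csv(paths[["edges"]])
  expect_equal(nrow(edges), igraph::ecount(g))
})
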