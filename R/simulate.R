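# Synthetic data: drug-impurity-like structure sets for the curation
# module, and multi-vendor multi-version categorical prediction histories
# with controlled initial marginals and transition kernels.

#' Describe one synthetic model's version history
#'
#' @param vendor vendor name (use a vendor present in the vocabulary map so
#'   the simulated raw terms can be harmonized end-to-end).
#' @param model_type `"statistical"` or `"rule_based"`.
#' @param versions character vector of version labels, in release order.
#' @param release_years integer vector parallel to `versions`.
#' @param initial named probability 4-vector over the call categories for
#'   the first version.
#' @param kernel 4x4 row-stochastic transition matrix applied at every
#'   version step, or a list of such matrices (one per step).
#' @return A `history_model` list.
#' @export
history_model <- function(vendor, model_type, versions, release_years,
                          initial, kernel) {
  stopifnot(model_type %in% MODEL_TYPES,
            length(versions) >= 1,
            length(release_years) == length(versions))
  initial <- initial[CALL_LEVELS]
  if (anyNA(initial) || abs(sum(initial) - 1) > 1e-9 || any(initial < 0)) {
    stop("initial marginals must be a probability vector over ",
         paste(CALL_LEVELS, collapse = ", "), call. = FALSE)
  }
  n_steps <- length(versions) - 1L
  if (!is.list(kernel)) kernel <- rep(list(kernel), n_steps)
  if (length(kernel) != n_steps) {
    stop("need one kernel per version step (", n_steps, ")", call. = FALSE)
  }
  for (k in kernel) {
    stopifnot(is.matrix(k), all(dim(k) == c(4, 4)))
    if (!all(rownames(k) == CALL_LEVELS) || !all(colnames(k) == CALL_LEVELS)) {
      stop("kernels must have rows/columns named ",
           paste(CALL_LEVELS, collapse = ", "), call. = FALSE)
    }
    if (any(k < 0) || any(abs(rowSums(k) - 1) > 1e-9)) {
      stop("kernel rows must each sum to 1", call. = FALSE)
    }
  }
  structure(list(vendor = vendor, model_type = model_type,
                 versions = versions,
                 release_years = as.integer(release_years),
                 initial = initial, kernel = kernel),
            class = "history_model")
}

#' Specification of a synthetic prediction history
#'
#' @param n_compounds number of compounds (>= 1).
#' @param models list of [history_model()]s.
#' @param seed integer seed; the whole simulation is reproducible given it.
#' @param coupling in `[0, 1]`: strength with which a shared latent
#'   "true mutagenicity" Bernoulli per compound couples the initial calls
#'   of a vendor's models (0 = independent models).
#' @param p_mutagenic probability of the latent Bernoulli.
#' @return A `history_spec` list.
#' @export
history_spec <- function(n_compounds, models, seed = 1L, coupling = 0,
                         p_mutagenic = 0.3) {
  stopifnot(n_compounds >= 1, length(models) >= 1,
            coupling >= 0, coupling <= 1,
            p_mutagenic >= 0, p_mutagenic <= 1)
  for (m in models) stopifnot(inherits(m, "history_model"))
  structure(list(n_compounds = as.integer(n_compounds), models = models,
                 seed = as.integer(seed), coupling = coupling,
                 p_mutagenic = p_mutagenic),
            class = "history_spec")
}

# Default per-step transition kernel: mostly-stable calls with small
# drift rates of the order reported for real model updates (cumulative
# negative-to-positive changes of a few percent over two steps).
default_kernel <- function() {
  k <- matrix(c(
    # to: POSITIVE NEGATIVE EQUIVOCAL   OOD     (from:)
    0.955,    0.025,   0.018, 0.002,  # POSITIVE
    0.010,    0.966,   0.020, 0.004,  # NEGATIVE
    0.020,    0.030,   0.945, 0.005,  # EQUIVOCAL
    0.004,    0.020,   0.004, 0.972), # OOD
    nrow = 4, byrow = TRUE,
    dimnames = list(CALL_LEVELS, CALL_LEVELS))
  k
}

# Drop a category from a kernel (for models that cannot emit it): its
# column mass is folded into NEGATIVE and its row becomes inert.
forbid_category <- function(k, call) {
  k[, "NEGATIVE"] <- k[, "NEGATIVE"] + k[, call]
  k[, call] <- 0
  k[call, ] <- 0
  k[call, call] <- 1
  k
}

#' Default synthetic study specification
#'
#' Three vendors, each with one statistical and one rule-based model and
#' versions released in 2014, 2016 and 2018, over `n_compounds` compounds
#' (default 3367, the size of the curated impurity-like dataset the
#' published category counts refer to). Initial marginals are typical of
#' the published per-version category distributions (roughly 20-30%
#' positive, 60-65% negative, the rest equivocal or out-of-domain); the
#' rule-based model of the `Lhasa` vendor never emits `EQUIVOCAL`, matching
#' its vocabulary. The per-step kernel drifts a few percent of compounds
#' per update.
#'
#' @param n_compounds compound count.
#' @param seed integer seed.
#' @param coupling stat/rule coupling (default 0.5).
#' @return A [history_spec()].
#' @export
default_history_spec <- function(n_compounds = 3367, seed = 1L,
                                 coupling = 0.5) {
  years <- c(2014L, 2016L, 2018L)
  stat_init <- c(POSITIVE = 0.20, NEGATIVE = 0.63, EQUIVOCAL = 0.12,
                 OOD = 0.05)
  rule_init <- c(POSITIVE = 0.30, NEGATIVE = 0.645, EQUIVOCAL = 0.015,
                 OOD = 0.04)
  lh_rule_init <- c(POSITIVE = 0.30, NEGATIVE = 0.63, EQUIVOCAL = 0,
                    OOD = 0.07)
  k <- default_kernel()
  models <- list(
    history_model("Leadscope", "statistical", c("S1", "S2", "S3"), years,
                  stat_init, k),
    history_model("Leadscope", "rule_based", c("R1", "R2", "R3"), years,
                  rule_init, k),
    history_model("MultiCASE", "statistical", c("S1", "S2", "S3"), years,
                  stat_init, k),
    history_model("MultiCASE", "rule_based", c("R1", "R2", "R3"), years,
                  rule_init, k),
    history_model("Lhasa", "statistical", c("S1", "S2", "S3"), years,
                  stat_init, k),
    history_model("Lhasa", "rule_based", c("R1", "R2", "R3"), years,
                  lh_rule_init, forbid_category(k, "EQUIVOCAL")))
  history_spec(n_compounds, models, seed = seed, coupling = coupling)
}

sample_calls <- function(prob) {
  # one draw per row of a probability matrix
  cum <- t(apply(prob, 1, cumsum))
  cum[, 4] <- 1  # guard against cumulative rounding
  u <- stats::runif(nrow(prob))
  CALL_LEVELS[max.col(u <= cum, ties.method = "first")]
}

#' Simulate a multi-vendor prediction history
#'
#' For each model, per-compound calls at the first version are drawn from
#' the model's initial marginals (optionally tilted by a shared latent
#' "true mutagenicity" Bernoulli that couples a vendor's two models), then
#' evolved version-to-version by the transition kernel, independently per
#' compound. Fully reproducible for a fixed seed.
#'
#' @param spec a [history_spec()].
#' @param map vocabulary map used to express calls as vendor raw terms;
#'   the returned table carries a `raw_call` column in each vendor's own
#'   vocabulary so that harmonization is exercised end-to-end.
#' @return Tibble `compound_id`, `vendor`, `model_type`, `version_label`,
#'   `release_year`, `raw_call` (plus the generating `call`).
#' @export
simulate_history <- function(spec, map = load_vocab_map()) {
  stopifnot(inherits(spec, "history_spec"))
  n <- spec$n_compounds
  ids <- sprintf("cmpd_%05d", seq_len(n))
  withr::with_seed(spec$seed, {
    latent <- stats::runif(n) < spec$p_mutagenic
    rows <- lapply(spec$models, function(m) {
      init <- matrix(rep(m$initial, each = n), nrow = n,
                     dimnames = list(NULL, CALL_LEVELS))
      if (spec$coupling > 0) {
        pos_target <- c(POSITIVE = 1, NEGATIVE = 0, EQUIVOCAL = 0, OOD = 0)
        nonpos <- m$initial
        nonpos["POSITIVE"] <- 0
        if (sum(nonpos) > 0) nonpos <- nonpos / sum(nonpos)
        target <- matrix(NA_real_, nrow = n, ncol = 4,
                         dimnames = list(NULL, CALL_LEVELS))
        target[latent, ] <- matrix(rep(pos_target, each = sum(latent)),
                                   ncol = 4)
        target[!latent, ] <- matrix(rep(nonpos, each = sum(!latent)),
                                    ncol = 4)
        init <- (1 - spec$coupling) * init + spec$coupling * target
      }
      calls <- vector("list", length(m$versions))
      calls[[1]] <- sample_calls(init)
      if (length(m$versions) > 1) {
        for (step in seq_len(length(m$versions) - 1L)) {
          k <- m$kernel[[step]]
          prev <- calls[[step]]
          nxt <- character(n)
          for (f in CALL_LEVELS) {
            idx <- which(prev == f)
            if (length(idx) == 0) next
            nxt[idx] <- sample(CALL_LEVELS, length(idx), replace = TRUE,
                               prob = k[f, ])
          }
          calls[[step + 1L]] <- nxt
        }
      }
      dplyr::bind_rows(lapply(seq_along(m$versions), function(v) {
        tibble::tibble(compound_id = ids, vendor = m$vendor,
                       model_type = m$model_type,
                       version_label = m$versions[v],
                       release_year = m$release_years[v],
                       call = calls[[v]])
      }))
    })
  })
  out <- dplyr::bind_rows(rows)
  out$raw_call <- calls_to_raw_terms(out$call, out$vendor, out$model_type,
                                     map)
  out[c("compound_id", "vendor", "model_type", "version_label",
        "release_year", "raw_call", "call")]
}

#' Express harmonized calls as vendor raw terms
#'
#' Inverse of [harmonize_call()]: picks, for each (vendor, model type,
#' call), the first raw term the vocabulary map assigns to that call.
#' Errors if a model has no term for a requested call (e.g. `EQUIVOCAL`
#' for a rule-based system that cannot emit it).
#'
#' @param call character vector of calls.
#' @param vendor,model_type model identity vectors.
#' @param map a [load_vocab_map()] result.
#' @return Character vector of raw terms.
#' @export
calls_to_raw_terms <- function(call, vendor, model_type,
                               map = load_vocab_map()) {
  stopifnot(inherits(map, "vocab_map"))
  e <- map$entries
  first <- e[!duplicated(paste(e$vendor, e$model_type, e$call, sep = "\r")), ]
  idx <- match(paste(vendor, model_type, as_call(call), sep = "\r"),
               paste(first$vendor, first$model_type, first$call, sep = "\r"))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("no raw term for call ", call[miss], " of model ", vendor[miss],
         "/", model_type[miss], call. = FALSE)
  }
  first$raw_term[idx]
}

# Scaffold and substituent grammar for impurity-like structures. The
# substituents echo common mutagenicity alert classes (aryl amines,
# nitroaromatics, acyl halides, esters, aldehydes, alkyl halides,
# epoxides, boronic acids, ...).
STRUCTURE_SCAFFOLDS <- c(
  "c1ccc(%s)cc1", "c1cc(%s)ccc1%s", "c1ccc(%s)nc1", "c1cc(%s)cnc1%s",
  "c1ccc2cc(%s)ccc2c1", "c1cc(%s)oc1", "c1cc(%s)sc1",
  "C1CCC(%s)CC1", "CC(%s)CC", "CCC(%s)C%s", "CC(C)(%s)C")

STRUCTURE_SUBSTITUENTS <- c(
  "N", "NC", "[N+](=O)[O-]", "C(=O)Cl", "C(=O)OC", "C(=O)OCC", "C=O",
  "CCl", "CBr", "OC", "O", "C", "CC", "CCC", "F", "Cl", "Br", "C#N",
  "B(O)O", "NN", "OS(=O)(=O)C", "C9CO9", "C(=O)C=C", "S", "SC")

#' Generate drug-impurity-like structures
#'
#' Assembles small organic SMILES from a scaffold + substituent grammar
#' whose functional groups echo common bacterial-mutagenicity alert
#' classes. A configurable fraction of records are made defective —
#' mixtures, metal-containing structures, invalid lines, exact duplicates
#' or group I/II salts — to exercise the standardization filters.
#' Deterministic per seed.
#'
#' @param n number of structures (>= 1).
#' @param seed integer seed.
#' @param defect_fraction fraction in `[0, 1]` of records to make
#'   defective.
#' @param defect_types subset of
#'   `c("mixture", "metal", "invalid", "duplicate", "salt")`.
#' @param prefix id prefix (use distinct prefixes for query and reference
#'   sets).
#' @return Tibble `compound_id`, `smiles`.
#' @export
generate_structures <- function(n, seed = 1L, defect_fraction = 0,
                                defect_types = c("mixture", "metal",
                                                 "invalid", "duplicate",
                                                 "salt"),
                                prefix = "gen") {
  stopifnot(n >= 1, defect_fraction >= 0, defect_fraction <= 1)
  defect_types <- match.arg(defect_types, several.ok = TRUE)
  withr::with_seed(seed, {
    smiles <- vapply(seq_len(n), function(i) {
      tmpl <- sample(STRUCTURE_SCAFFOLDS, 1)
      n_slots <- lengths(regmatches(tmpl, gregexpr("%s", tmpl, fixed = TRUE)))
      subs <- sample(STRUCTURE_SUBSTITUENTS, n_slots, replace = TRUE)
      do.call(sprintf, c(list(tmpl), as.list(subs)))
    }, character(1))
    n_defect <- round(n * defect_fraction)
    if (n_defect > 0) {
      idx <- sample.int(n, n_defect)
      kinds <- sample(defect_types, n_defect, replace = TRUE)
      for (j in seq_along(idx)) {
        i <- idx[j]
        smiles[i] <- switch(
          kinds[j],
          mixture = paste0(smiles[i], ".", "CCOCC"),
          metal = paste0(smiles[i], ".[Zn+2]"),
          invalid = paste0(smiles[i], "%99"),  # unclosed ring-bond label
          duplicate = smiles[(i %% n) + 1L],
          salt = paste0("c1ccc(C(=O)[O-])cc1", ".[Na+]"))
      }
    }
  })
  tibble::tibble(compound_id = sprintf("%s_%05d", prefix, seq_len(n)),
                 smiles = smiles)
}
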