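---
title: "Methods: curation, harmonization, consensus and version-drift analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, harmonization, consensus and version-drift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsardrift)
```

## Scope

Regulatory assessment of mutagenic impurities in pharmaceuticals (the ICH
M7 framework) rests on two complementary (Q)SAR methodologies — one
statistical, one expert rule-based — whose vendors update models over
time. An impurity judged negative under one software version may be
called positive by a later one, so the stability of calls across versions
is a practical safety question. `qsardrift` implements the full analysis
pipeline for studying that stability: curation of a chemical-space-matched
compound set, harmonization of vendor vocabularies to a common
four-category scale, two-model consensus calls, and transition-matrix
analysis of version-to-version changes. Because the commercial models
themselves are proprietary, the package pairs the analysis machinery with
a synthetic generator of prediction histories, so every stage is testable
end to end.

## Structure standardization

`standardize_structures()` applies, in a fixed order, the policy used to
build an impurity-like dataset:

1. **Validation** — the raw line must parse as a structure (OpenBabel);
   failures are recorded as `REJECTED / INVALID`, never raised as errors,
   so a curation run always yields one record per input line.
2. **Contextualization** — stereochemistry (bond marks and chirality
   tags) and isotope labels are removed before parsing. Both encode
   information irrelevant to fragment-level mutagenicity assessment.
   Explicit hydrogen counts inside bracket atoms are preserved, so
   valence is unaffected.
3. **Element policy** — allowed elements are the organic subset
   (H, B, C, N, O, F, Si, P, S, Cl, Br, I, Se) plus group I/II metals;
   any other element rejects the record with `DISALLOWED_METAL`. The
   group I/II exception exists so that common pharmaceutical counterions
   survive the next step.
4. **Counterion stripping and the mixture test** — bare group I/II ions
   (`[Na+]`, `[Ca+2]`, ...) are removed as components; if more than one
   component remains the record is `REJECTED / MIXTURE`. A sodium
   carboxylate therefore standardizes to the neutral parent acid, while
   a genuine two-organic mixture is rejected.
5. **Neutralization and canonicalization** — remaining charges are
   neutralized where valence allows, and the survivor is written as a
   canonical SMILES. Canonicalization makes structural identity a string
   comparison, which `exclude_known()` exploits.

The reject reasons are assigned in the fixed order `INVALID` →
`DISALLOWED_METAL` → `MIXTURE`: a ferrocene-contaminated mixture is
reported as a metal problem, not a mixture. Standardization is idempotent
— re-standardizing its own output returns it unchanged — which the test
suite asserts on generated structures.

## Fragment fingerprints and similarity

`fragment_fingerprint()` enumerates every linear atom–bond path of 0 to
`depth` bonds (default 7), with atoms typed by element and aromaticity
and bonds by order. Each path is written in its lexicographically smaller
read direction and hashed with a 31-bit polynomial rolling hash; a
fingerprint is the *set* of these identifiers. A 31-bit space is used
because R has no native 64-bit integer; at realistic fragment counts
(tens of thousands of distinct fragments per dataset) the expected number
of collisions is far below one per dataset and has no practical effect
on Tanimoto values.

Similarity is the Tanimoto coefficient over bit sets,

$$T(A, B) = \frac{|A \cap B|}{|A \cup B|},$$

with the degenerate convention \(T(\emptyset, \emptyset) = 1\) (two empty
molecules are identical). Fingerprints carry their depth, and comparing
fingerprints from different depth settings is a configuration error, not
a silent 0.

`select_similar()` keeps each query compound whose *maximum* similarity
to any reference compound is at least the cutoff (default 0.5,
inclusive). Selection is deliberately query→reference and set-valued: a
query compound matching several reference compounds is selected once.
Selection is monotone in the cutoff, which the suite asserts.

`build_similarity_graph()` thresholds all pairwise similarities, within
and between the two datasets, and reports connected components and
singletons. Force-directed layout is presentation, not analysis: the
graph is exported as GraphML plus an edge-list CSV for external viewers.

## Alert profiling

`profile_alerts()` counts, per named SMARTS pattern, the compounds with
at least one match — a compound counts once per alert no matter how many
sites match — and bins everything outside the `top_k` most frequent
alerts into `"other"`, breaking ties at the boundary by alert name. The
shipped alert set (`read_smarts()`) is a small generic collection of
public bacterial-mutagenicity toxicophores (aromatic nitro and amine
groups, N-nitroso, epoxides, acyl and alkyl halides, aldehydes, boronic
acids, Michael acceptors, ...); it is not, and does not attempt to
reproduce, any vendor's proprietary alert definitions.

## Vocabulary harmonization

Vendors name the same four outcomes differently. `load_vocab_map()` reads
a YAML mapping (vendor, model type, raw term) → call; the shipped default
covers three vendors' statistical and rule-based systems. Matching is
exact after trimming and case-folding. Three conventions are encoded for
the expert rule-based system that reports structural alerts with
reasoning levels rather than a flat call:

* an alerting structure with reasoning of *equivocal or higher* is a
  **positive** call (one map entry per reasoning level, since exports
  name the level);
* a negative with *misclassified* features remains **negative**;
* a negative with *unclassified* features is treated as **out-of-domain**
  (`OOD`) — the compound contains features the model's reference data do
  not cover, which is how practitioners commonly manage such output even
  though the vendor does not label it OOD.

That system has no equivocal output; its map entry declares
`forbidden_calls: [EQUIVOCAL]` and the loader rejects any config that
maps a term onto a forbidden call. `harmonize_table()` maps a raw
prediction CSV and then validates the result as a *complete* matrix:
every compound has exactly one call for every listed model version, with
duplicates and gaps reported with their coordinates. Terms missing from
the map are data errors naming the term and model — harmonization is
total or it fails loudly.

## Consensus calls

`consensus_call()` combines one statistical and one rule-based call:

* positive if **either** model is positive;
* else equivocal if either is equivocal;
* negative only if **both** are negative;
* a negative paired with an OOD, or two OODs, give OOD.

Two equivocal calls are not covered by the enumerated rules; they resolve
to equivocal, the conservative extension consistent with the severity
order the rules imply. The whole rule list is equivalent to a maximum
under `POSITIVE > EQUIVOCAL > OOD > NEGATIVE`, and the test suite checks
the rule-by-rule implementation against an independently coded
severity-max oracle on all 16 ordered pairs. Consensus is defined only
for statistical × rule-based pairs, mirroring the requirement of two
complementary methodologies; the API resolves members by model type, so
same-type pairs cannot be formed.

```{r consensus-demo}
consensus_call(c("NEGATIVE", "EQUIVOCAL", "NEGATIVE"),
               c("POSITIVE", "OOD", "OOD"))
```

## Change analysis

`transition_matrix()` cross-tabulates one model's calls at two versions;
the trace is the unchanged count. The default comparison is *cumulative*:
the earliest version inside the configured year window against the
latest (the window, e.g. 2014–2018, is a filter, not a constant).
`change_percentages()` offers two denominators:

* `"total"` — every cell divided by the compound total, matching the
  "x% of the compounds" convention used in published drift reports; the
  16 cells sum to 100%.
* `"from_category"` — rows divided by their own sums (conditional rates,
  the natural scale for statements like "of the OOD compounds, y%
  became negative"); a category with no compounds yields `NaN`,
  deliberately distinct from 0.

`combination_grid()` enumerates the full statistical × rule-based product
across vendors, labelled intra-/inter-vendor; `unchanged_report()` and
`summarize_combination_changes()` aggregate per-combination consensus
transitions with the arithmetic mean (the averaging granularity — over
combinations — is a function argument away from over-vendor or
over-model groupings, since published figures are ambiguous on this
point). `conservation_check()` guards the bookkeeping invariant that
every version's four category counts sum to the compound total; applied
to the shipped fixture of published per-version counts it *flags* the
rows whose printed values do not sum to the stated dataset size (several
do), and never corrects them.

```{r changes-demo}
tab <- prediction_table(tibble::tibble(
  compound_id = rep(sprintf("c%d", 1:5), 2),
  vendor = "V", model_type = "statistical",
  version_label = rep(c("v1", "v2"), each = 5),
  release_year = rep(c(2014L, 2018L), each = 5),
  call = c("POSITIVE", "NEGATIVE", "NEGATIVE", "EQUIVOCAL", "OOD",
           "NEGATIVE", "NEGATIVE", "POSITIVE", "EQUIVOCAL", "OOD")))
tm <- transition_matrix(tab, "V", "statistical", "v1", "v2")
attr(change_percentages(tm, "total"), "unchanged_percent")
```

## The synthetic generator

`simulate_history()` draws, per model, each compound's call at the first
version from an initial marginal distribution and evolves it
version-to-version with a 4×4 row-stochastic kernel, independently per
compound. All randomness comes from one integer seed, making the whole
downstream pipeline bit-reproducible. An optional coupling parameter ties
a vendor's two models to a shared latent "truly mutagenic" Bernoulli per
compound: with coupling \(c\), a model's initial distribution is the
\((1-c)\)-weighted marginal blended with a latent-conditional target
(point mass on positive for latent positives, the positive-free
renormalized marginal otherwise). This is a modeling choice — the
simplest mechanism that makes two models agree more often than chance,
as real models assessing the same chemistry do.

Defaults (`default_history_spec()`) define the study conditions: 3367
compounds (the published curated-dataset size); three vendors × two model
types; versions released 2014, 2016, 2018; initial marginals of roughly
20–30% positive, 60–65% negative and the remainder equivocal/OOD, shaped
like the published per-version category counts; a per-step kernel whose
drift rates (about 1–3% off-diagonal) produce cumulative changes of the
few-percent order reported for real model updates; coupling 0.5. The
rule-based model of one vendor never emits equivocal, exercising the
forbidden-call path end to end (its kernel folds the equivocal column
into negative).

`generate_structures()` assembles impurity-like SMILES from a scaffold +
substituent grammar whose functional groups echo common alert classes,
with a configurable fraction of deliberately defective records
(mixtures, disallowed metals, invalid lines, duplicates, group I/II
salts) to exercise every standardization filter.

**What the generator does not emulate.** Calls are independent of the
generated structures — there is no structure–activity relationship — and
kernels are homogeneous over compounds, whereas real updates target
specific chemical classes. Passing tests therefore demonstrate the
correctness of the bookkeeping, harmonization, consensus and counting
machinery under known conditions, not predictive validity on real
chemistry.

### A note on consensus damping

Published drift analyses observe that combining two complementary models
reduces negative-to-positive changes. Under *strict independence* this
is not a mathematical necessity: a consensus negative requires both
members negative, so the conditional exit rate toward positive is
roughly twice a single model's. The observed damping, on the
total-compound scale, comes from two effects the pipeline makes
explicit: far fewer compounds are consensus-negative than single-model
negative, and correlated models (the coupled generator, like real
software assessing the same structures) flip together rather than
doubling their chances. The suite asserts the damping property on the
total-denominator rates under the generator's default coupling.

## Problem sizes and numerical choices

Test and script workloads are sized for quick, deterministic runs:
curation examples use pools of 25–400 generated structures; oracle
equivalence for the transition machinery runs 100 random tables of up to
200 compounds; kernel-recovery and damping checks simulate 10,000
compounds for one version step (3 binomial standard errors as the
acceptance band); the full drift study uses the 3367-compound default.
Tolerances elsewhere are exact: counting, harmonization and consensus are
integer/categorical operations with no floating-point slack, and marginal
and kernel validation uses 1e-9 on probability sums.

## Known limitations

* Standardization and parsing inherit OpenBabel's SMILES dialect;
  exotic valence models may canonicalize differently in other toolkits.
* The fragment grammar is linear paths only; branched or ring-closure
  fragments are not enumerated. This matches the level of detail the
  similarity screen needs, but it is a documented stand-in, not a
  reimplementation of any specific published fingerprinting method.
* Charge neutralization covers cases where a proton can be added or
  removed without valence violation; permanently charged species (e.g.
  quaternary ammonium salts with non-group-I/II counterions) are
  rejected as mixtures by design.
* The published-counts fixture reproduces printed tables verbatim,
  including their internal inconsistencies; the conservation checker
  reports them and takes no view on their cause.
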