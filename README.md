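# qsardrift

Version-drift analysis for ICH M7 (Q)SAR mutagenicity predictions.

Pharmaceutical impurity assessment under the ICH M7 guideline combines
two complementary (Q)SAR models — one statistical, one expert rule-based
— into a single consensus call per compound. Vendors update these models
regularly, and an impurity judged negative years ago may be called
positive by today's model. `qsardrift` is for computational toxicologists
and regulatory scientists who need to quantify that drift: it curates a
chemical-space-matched compound set, harmonizes vendor-specific
prediction vocabularies onto a common four-category scale (`POSITIVE`,
`NEGATIVE`, `EQUIVOCAL`, `OOD`), forms consensus calls, and
cross-tabulates version-to-version changes. Since the commercial models
are proprietary, the package also ships a synthetic generator of
multi-vendor prediction histories so the entire pipeline runs and is
tested without any vendor software.

## Methods at a glance

* **Curation** — structures are standardized (validation, stereo/isotope
  removal, group I/II counterion stripping, mixture and metal filters,
  charge neutralization), fingerprinted as hashed sets of linear
  atom–bond paths (depth ≤ 7 bonds, atoms typed by element and
  aromaticity), and screened against a reference set with the Tanimoto
  coefficient T(A,B) = |A∩B| / |A∪B|, keeping query compounds with
  max-similarity ≥ 0.5. A thresholded similarity graph (components,
  singletons; GraphML export) and a SMARTS structural-alert frequency
  profile describe the resulting chemical space.
* **Harmonization** — a YAML vocabulary map sends each (vendor, model
  type, raw term) to one of the four categories; the shipped default
  covers three vendors, including the rule-based reasoning-level
  conventions (alerting at equivocal-or-higher ⇒ positive, misclassified
  features ⇒ negative, unclassified features ⇒ out-of-domain).
* **Consensus** — per compound, the combined call of one statistical and
  one rule-based model is the maximum under
  POSITIVE > EQUIVOCAL > OOD > NEGATIVE (positive if either member is
  positive; negative only if both are).
* **Change analysis** — for each model or consensus combination, a 4×4
  transition matrix between an initial and a contemporary version;
  change percentages per category pair (per-total or per-category
  denominators), unchanged percentages, per-version marginal counts, and
  the intra-/inter-vendor combination grid with means across
  combinations. A conservation checker verifies that every version's
  category counts sum to the compound total — including on a shipped
  fixture of published per-version counts, where it flags the printed
  rows that do not.

## Worked example

The `analysis/` directory holds the numbered workflow. Step by step:

```sh
Rscript analysis/01_generate_structures.R   # synthetic query + reference pools
Rscript analysis/02_curate.R                # standardize, select, graph, alerts
Rscript analysis/03_simulate_predictions.R  # 3367-compound prediction history
Rscript analysis/04_change_analysis.R       # harmonize + drift report
Rscript analysis/05_published_tables_check.R
```

Step 2 prints the curation funnel and chemical-space summary for a
400-structure pool with 15% deliberately defective records:

```
standardization funnel:
DISALLOWED_METAL          INVALID             KEPT          MIXTURE
              13               15              363                9
selected at Tanimoto >= 0.5: 279 | after exclusion: 251
similarity graph: 483 nodes, 2459 edges, 38 components ( 6 singletons )
```

i.e. 363 of 400 records survive standardization (the rest are rejected
with an explicit reason), 279 are similar enough to the reference set to
be kept, and 251 remain after removing structures present in the
exclusion list. Step 4 summarizes the simulated 2014–2018 drift of the
nine statistical × rule-based consensus combinations:

```
mean unchanged consensus predictions 2014-2018: 90.7%
mean consensus negative-to-positive change: 1.4% of compounds
```

Step 5 checks the published per-version category counts: 31 of 39 rows
sum to the stated 3367-compound total, and the remaining rows are listed
verbatim as printed-table inconsistencies (flagged, never corrected).
All tables land under `results/`.

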