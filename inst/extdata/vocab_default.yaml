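# Default vocabulary map: vendor/model-specific prediction terms to the
# common four-category scale (POSITIVE, NEGATIVE, EQUIVOCAL, OOD).
# Matching is case-insensitive after trimming when `normalize` is true.
# The Lhasa rule-based system has no equivocal output term: alerting
# structures with reasoning of equivocal or higher are positive calls,
# negatives with misclassified features are negative, and negatives with
# unclassified features are treated as out-of-domain.
normalize: true
vendors:
- vendor: Leadscope
  model_type: statistical
  terms:
    Positive: POSITIVE
    Negative: NEGATIVE
    Indeterminate: EQUIVOCAL
    Not in domain: OOD
- vendor: Leadscope
  model_type: rule_based
  terms:
    Positive: POSITIVE
    Negative: NEGATIVE
    Indeterminate: EQUIVOCAL
    Not in domain: OOD
- vendor: MultiCASE
  model_type: statistical
  terms:
    Positive: POSITIVE
    Negative: NEGATIVE
    Inconclusive: EQUIVOCAL
    Out of domain: OOD
- vendor: MultiCASE
  model_type: rule_based
  terms:
    Positive: POSITIVE
    Negative: NEGATIVE
    Inconclusive: EQUIVOCAL
    Out of domain: OOD
- vendor: Lhasa
  model_type: statistical
  terms:
    Positive: POSITIVE
    Negative: NEGATIVE
    Equivocal: EQUIVOCAL
    Outside domain: OOD
- vendor: Lhasa
  model_type: rule_based
  forbidden_calls: [EQUIVOCAL]
  terms:
    Alerting structure (certain): POSITIVE
    Alerting structure (probable): POSITIVE
    Alerting structure (plausible): POSITIVE
    Alerting structure (equivocal): POSITIVE
    Negative: NEGATIVE
    Negative with misclassified features: NEGATIVE
    Negative with unclassified features: OOD
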