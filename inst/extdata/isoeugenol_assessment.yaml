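# Risk-assessment configuration for isoeugenol: POD is the BMDL of
# 8 mg/kg bw/day (8000 ug) for hepatocellular adenoma; uncertainty factors
# follow the CVMP ledger minus the LOAEL-to-NOAEL factor of 2, which a
# BMDL-based POD does not need.
pod: 8000            # ug/kg bw/day
pod_type: bmdl
uncertainty_factors:
  interspecies_intraspecies: 100
  severity_and_study_deficiencies: 5
body_weight: 60      # kg, JECFA convention
exposures:           # ug/kg bw/day, food + consumer products
  europe: 2.35
  usa: 1.12
daily_food_intake: 0.3   # kg fish per day
allocation: 0.4          # share of the acceptable intake allotted to fish
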