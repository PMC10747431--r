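# Bundled dose-response datasets

Summarized endpoints from the NTP isoeugenol gavage studies in F344/N rats
and B6C3F1 mice (NTP Technical Report 551), as used in the package's worked
examples and validation suite. Quantal files carry `dose` (mg/kg bw/day),
`n` (animals examined) and `affected`; the continuous body-weight file
carries `dose`, `n`, `mean` and `sd` (grams, study termination).

| file | endpoint | species/sex | study |
|---|---|---|---|
| hepatocellular_adenoma_mouse_male_2yr.csv | hepatocellular adenoma (incl. multiple) | mouse, male | 2 years |
| hepatocellular_carcinoma_mouse_male_2yr.csv | hepatocellular carcinoma (incl. multiple) | mouse, male | 2 years |
| hepatocellular_adenoma_carcinoma_mouse_male_2yr.csv | adenoma and/or carcinoma combined | mouse, male | 2 years |
| histiocytic_sarcoma_mouse_female_2yr.csv | histiocytic sarcoma (multiple sites) | mouse, female | 2 years |
| thymoma_rat_male_2yr.csv | thymoma (benign or malignant) | rat, male | 2 years |
| mammary_gland_carcinoma_rat_male_2yr.csv | mammary gland carcinoma | rat, male | 2 years |
| olfactory_atrophy_rat_female_3mo.csv | atrophy of the olfactory epithelium | rat, female | 3 months |
| olfactory_atrophy_rat_male_3mo.csv | atrophy of the olfactory epithelium | rat, male | 3 months |
| body_weight_rat_male_3mo.csv | terminal body weight | rat, male | 3 months |

Provenance note: group sizes are not reported alongside the male-rat
body-weight means; they are taken as 10 per group, the design of the
3-month rat study (the same denominators as the 3-month incidence tables).

`isoeugenol_assessment.yaml` is a ready-made configuration for
`read_assessment()`, chaining the BMDL-based POD through the
uncertainty-factor ledger to the ADI, MRL and margins of exposure.
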