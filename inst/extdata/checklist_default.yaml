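# Default readiness checklists: an intervention is "ready" at a facility
# only if ALL listed items were observed on the day of assessment.
# These defaults are a documented, editable stand-in for survey-specific
# readiness definitions; override with your own YAML of the same shape.
syphilis:
  - syphilis_test
  - syphilis_treatment_drug
diabetes:
  - glucose_test
  - diabetes_drug
hypertensive:
  - bp_apparatus
  - antihypertensive_drug
malaria:
  - malaria_diagnostic
  - antimalarial_drug
preeclampsia:
  - bp_apparatus
  - urine_protein_test
  - magnesium_sulphate
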