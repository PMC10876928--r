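# protscan run configuration template.
# Every key is optional; values shown are the shipped defaults for the
# targeted (two-centre) panel mode. See ?default_run_config and
# ?cohort_config for the full dictionaries.

panel_mode: targeted          # targeted | exploratory

stages:                       # stage toggles, executed in this order
  simulate: true
  qc: true
  scan: true
  predict: true
  power: true

paths:                        # used when simulate is disabled
  cohort: null                # participant TSV (see ?write_cohort)
  npx: null                   # Olink-style long CSV (see ?write_npx_long)

generator:                    # cohort_config() overrides
  n_cases: 796
  n_controls: 781
  n_proteins: 163
  horizon: 36                 # months
  batch_sd: 0.5               # NPX units, centre-B shift spread
  missing_rate: 0.02

qc:
  max_missing: 0.10           # per-centre rule for the targeted panel
  rule: per_centre            # per_centre | overall
  drop_qc_warning: true
  n_pcs: 10
  outlier_sd: .inf            # PCA outlier threshold (exploratory: 5)

scan:
  alpha: 0.05
  ties: efron                 # efron | breslow

predict:
  n_folds: 5
  n_lambda: 50

power:
  target: 0.8                 # power target for the detectable effect
  hr_claim: 1.28              # hazard ratio whose power is reported
  reps: 100                   # replicates for the power-at-claim estimate
  bisect_reps: 100            # replicates per bisection evaluation
  bracket: [0.0, 1.5]         # log-HR search interval
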