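# Reference-scale configuration of the factorial simulation study.
# Keys mirror default_study_config(); read with read_study_config().
n: 10000
n_sim: 1000
m: 100
burn_in: 20
seed: 1
strict: true
population:
  prev: 0.15        # marginal binary-outcome prevalence
  log_or: 0.405     # full-population exposure log OR (OR 1.50)
  pi_x: 0.25        # exposure prevalence
  dicho: threshold  # dichotomisation of the latent score
mechanism:
  gy_or: 0.75       # observation OR per 1 SD of the latent outcome
  link: logit
aux:
  specificity: 0.975
factors:
  frac_missing: [0.2, 0.4, 0.6, 0.8]   # Factor 1
  sensitivity: [0.25, 0.75]            # Factor 2
  interaction: [false, true]           # Factor 3
  frac_missing_aux: [0.0, 0.25]        # Factor 4
factor4_fixed:      # Factors 2-3 in the nonzero Factor-4 block
  sensitivity: 0.75
  interaction: true
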