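# Replication configuration: the seven standard dose-conversion scenarios.
# Populations are 10 trials x 100 subjects (twin: 10 trials x 1); the
# master seed can be overridden from the command line or run_config().
seed: 1
victim_compound: tacrolimus
scenarios:
  - name: healthy
    population: {kind: healthy, n_trials: 10, n_per_trial: 100,
                 expressor_frequency: 0.17, seed_offset: 1}
  - name: virtual_twin
    population:
      kind: twin
      n_trials: 10
      n_per_trial: 1
      seed_offset: 2
      twin_covariates: {age: 70, sex: female, weight: 70, height: 163,
                        hematocrit: 0.237, cyp3a5_expressor: false}
  - name: both_expressor
    population: {kind: healthy, n_trials: 10, n_per_trial: 100,
                 expressor_frequency: 1.0, seed_offset: 3}
  - name: donor_expressor
    population: {kind: healthy, n_trials: 10, n_per_trial: 100,
                 expressor_frequency: 1.0, seed_offset: 4}
    recipient_expressor: false
  - name: recipient_expressor
    population: {kind: healthy, n_trials: 10, n_per_trial: 100,
                 expressor_frequency: 1.0, seed_offset: 5}
    donor_expressor: false
  - name: itraconazole_po
    population: {kind: healthy, n_trials: 10, n_per_trial: 100,
                 expressor_frequency: 0.17, seed_offset: 6}
    perpetrator: {compound: itraconazole, route: oral, dose: 200, interval: 24}
  - name: itraconazole_iv
    population: {kind: healthy, n_trials: 10, n_per_trial: 100,
                 expressor_frequency: 0.17, seed_offset: 7}
    perpetrator: {compound: itraconazole, route: iv_infusion, dose: 200,
                  interval: 24}
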