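frequency: monthly
input:
  scenario: demo_monthly_scenario.yaml
n_draws: 10000.0
seed: 1.0
figures: yes
out_dir: output
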