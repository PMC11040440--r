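# Packaged demonstration study: a scaled synthetic HDSS cohort run
# through the full discovery / temporal-validation pipeline.
seed: 20
sim:
  n_children: 10000
study:
  split_year: 2011
  min_count: 50
  cool_hidden: 8
  cool_epochs: 3000
  cool_restarts: 3
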