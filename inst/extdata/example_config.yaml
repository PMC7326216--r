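# anccap pipeline configuration (values omitted here keep their defaults)
seed: 42
simulate:
  genome_length: 16500
  gc: 0.4
  fragment:
    n_capture: 20000
    n_shotgun: 20000
  dup_rate: 0.15
analysis:
  min_depth: 3
  majority: 0.9
  min_mapq: 30
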