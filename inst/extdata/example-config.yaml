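# Example run configuration: the reference sRNA-feedback controller under
# the standard repeated-batch protocol.
topology: CLpATL
n_B: 300
genes:
  A:
    omega: 50.0       # process maximal transcription rate (mc/min)
  B:
    n_aa: 300         # controller protein length (aa)
    b: 1.0            # ribosome binding rate (1/mc/min)
  C:
    omega: 100.0      # sRNA promoter strength (mc/min)
params:
  k_B: 500.0          # activation threshold of the sRNA promoter (mc)
  k_seq: 0.1          # sRNA-mRNA co-degradation rate constant (1/mc/min)
host: {}              # defaults: published E. coli calibration
mutation:
  base_rate: 5.0e-5   # single-level promoter loss rate (1/min)
  attenuation: 0.1    # factor per extra level skipped
protocol:
  day_length: 1440    # min
  sample_size: 1000   # cells carried over at dilution
  substrate_reset: 1.0e+12
  max_days: 80
  stop_fraction: 0.01
solver:
  record_every: 20    # trace sampling interval (min)
seed: 1
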