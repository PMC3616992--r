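parental:
  .type: bik_params
  kS: 0.138888888888889
  kubi: 0.002777777777778
  Vmax: 0.0
  Km: 20.0
  kdeg: 1.0
src:
  .type: bik_params
  kS: 0.138888888888889
  kubi: 0.002777777777778
  Vmax: 0.359710144927536
  Km: 20.0
  kdeg: 1.0

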