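parental:
  .type: cell_line_spec
  label: parental
  Bik_ss: 50.0
  Bax_total: 48.0
  Bcl2_total: 545.0
  Bid_total: 52.0
  tBid0: 1.0
src:
  .type: cell_line_spec
  label: src
  Bik_ss: 9.199999999999999
  Bax_total: 100.0
  Bcl2_total: 600.0
  Bid_total: 40.0
  tBid0: 1.0

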