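# Example plate layout for a duplex WPRE/TERT VCN run: one sample well,
# its dilution, a non-transduced control and a no-template control.
wells:
  - well_id: A01
    sample_id: CAR-1
    role: sample
    dilution_factor: 1
    channel_map:
      target: FAM
      reference: HEX
  - well_id: A02
    sample_id: CAR-1
    role: sample
    dilution_factor: 0.5
    channel_map:
      target: FAM
      reference: HEX
  - well_id: B01
    sample_id: PBMC
    role: non_transduced_control
    dilution_factor: 1
  - well_id: H12
    sample_id: NTC
    role: ntc
    dilution_factor: 1
assay:
  droplet_volume_ul: 0.00085
  min_accepted_droplets: 10000
  threshold_method: otsu
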