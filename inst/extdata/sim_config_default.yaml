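region_length: 100000
modules:
  dennis:
  - 30000
  - 37000
  ray:
  - 40000
  - 77000
populations:
  name:
  - outgroup
  - silvaniform
  - elevatus
  - melpo_dr
  - melpo_pm
  - meriana
  - contigua
  - ray_anc
  - melpo_anc
  species:
  - aoede
  - silvaniform
  - elevatus
  - melpomene
  - melpomene
  - melpomene
  - timareta
  - melpomene
  - melpomene
  clade:
  - outgroup
  - silvaniform
  - silvaniform
  - melpomene
  - melpomene
  - melpomene
  - melpomene
  - melpomene
  - melpomene
  Ne:
  - 2000000.0
  - 1600000.0
  - 400000.0
  - 1600000.0
  - 1600000.0
  - 1600000.0
  - 1600000.0
  - 1600000.0
  - 800000.0
  n_hap:
  - 8.0
  - 20.0
  - 12.0
  - 32.0
  - 32.0
  - 4.0
  - 4.0
  - 0.0
  - 0.0
splits:
  pop:
  - meriana
  - contigua
  - melpo_dr
  - melpo_pm
  - ray_anc
  - elevatus
  - melpo_anc
  - silvaniform
  into:
  - melpo_dr
  - melpo_dr
  - melpo_pm
  - melpo_anc
  - melpo_anc
  - silvaniform
  - silvaniform
  - outgroup
  time:
  - 0.005
  - 0.005
  - 0.01
  - 1.0
  - 1.9
  - 3.0
  - 3.96
  - 8.0
mutation_rate: 0.005
generation_scale: 2.5e-07
introgression_events:
- name: dennis_into_melpomene
  time: 1.95
  donor: elevatus
  recipient: melpo_dr
  interval:
  - 30000
  - 37000
  fraction: 1.0
- name: ray_origin_melpomene
  time: 1.85
  donor: ray_anc
  recipient: melpo_dr
  interval:
  - 40000
  - 77000
  fraction: 1.0
- name: ray_into_elevatus
  time: 0.66
  donor: melpo_dr
  recipient: elevatus
  interval:
  - 40000
  - 77000
  fraction: 1.0
recombinant_specs:
- hap: meriana_01_h1
  breakpoint: 38200
  left_like: melpo_dr
  right_like: melpo_pm
- hap: meriana_01_h2
  breakpoint: 38200
  left_like: melpo_dr
  right_like: melpo_pm
- hap: meriana_02_h1
  breakpoint: 38200
  left_like: melpo_dr
  right_like: melpo_pm
- hap: meriana_02_h2
  breakpoint: 38200
  left_like: melpo_dr
  right_like: melpo_pm
- hap: contigua_01_h1
  breakpoint: 38800
  left_like: melpo_pm
  right_like: melpo_dr
- hap: contigua_01_h2
  breakpoint: 38800
  left_like: melpo_pm
  right_like: melpo_dr
- hap: contigua_02_h1
  breakpoint: 38800
  left_like: melpo_pm
  right_like: melpo_dr
- hap: contigua_02_h2
  breakpoint: 38800
  left_like: melpo_pm
  right_like: melpo_dr
native_modules:
  elevatus: dennis
recipient_clade: melpomene
indel_specs:
- module: dennis
  start: 31000
  end: 31400
  gap_in: outgroup
- module: dennis
  start: 33500
  end: 33620
  gap_in:
  - absent
  - outgroup
- module: dennis
  start: 35200
  end: 35280
  gap_in:
  - dennis
  - silvaniform
- module: ray
  start: 50000
  end: 50500
  gap_in: outgroup
- module: ray
  start: 55000
  end: 55150
  gap_in:
  - absent
  - outgroup
- module: ray
  start: 60000
  end: 60090
  gap_in: ray
coverage_model:
  mean_dp: 30.0
  gq_mean: 80.0
  gq_sd: 8.0
  mq_mean: 50.0
  mq_sd: 4.0
  low_call_frac: 0.02
  low_site_frac: 0.005
phase_scramble: no
seed: 1
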