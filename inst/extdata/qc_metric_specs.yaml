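# Default QC metric specifications. Thresholds t1 (Poor/Warning) and t2
# (Warning/Good) are field-standard defaults; override by passing your own
# file to read_metric_specs(). upper_bound: null selects the cohort rule
# (75th percentile + 1.5 * IQR); a number fixes the bounded-metric maximum.
- name: n_reads
  direction: higher_better
  min_value: 0
  t1: 1.0e7
  t2: 5.0e7
  upper_bound: null
  stage: alignment
- name: n_valid_pairs
  direction: higher_better
  min_value: 0
  t1: 5.0e6
  t2: 2.0e7
  upper_bound: null
  stage: alignment
- name: mean_mapping_pct
  direction: higher_better
  min_value: 0
  t1: 60
  t2: 80
  upper_bound: 100
  stage: alignment
- name: pct_valid_pairs
  direction: higher_better
  min_value: 0
  t1: 40
  t2: 60
  upper_bound: 100
  stage: alignment
- name: pct_duplicate_pairs
  direction: lower_better
  min_value: 0
  t1: 50
  t2: 80
  upper_bound: 100
  stage: alignment
- name: pct_cis_pairs
  direction: higher_better
  min_value: 0
  t1: 20
  t2: 40
  upper_bound: 100
  stage: alignment
- name: pct_cis_longrange_pairs
  direction: higher_better
  min_value: 0
  t1: 10
  t2: 25
  upper_bound: 100
  stage: alignment
- name: n_peaks
  direction: higher_better
  min_value: 0
  t1: 500
  t2: 5000
  upper_bound: null
  stage: peak_calling
- name: n_loops
  direction: higher_better
  min_value: 0
  t1: 1000
  t2: 10000
  upper_bound: null
  stage: loop_calling
- name: nrf
  direction: higher_better
  min_value: 0
  t1: 0.5
  t2: 0.8
  upper_bound: 1
  stage: chip_preprocessing
- name: pbc1
  direction: higher_better
  min_value: 0
  t1: 0.5
  t2: 0.9
  upper_bound: 1
  stage: chip_preprocessing
- name: pbc2
  direction: higher_better
  min_value: 0
  t1: 1
  t2: 3
  upper_bound: null
  stage: chip_preprocessing
- name: nsc
  direction: higher_better
  min_value: 1
  t1: 1.05
  t2: 1.1
  upper_bound: null
  stage: chip_preprocessing
- name: rsc
  direction: higher_better
  min_value: 0
  t1: 0.8
  t2: 1.0
  upper_bound: null
  stage: chip_preprocessing
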