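# Study configuration for the analysis workflow: three stations spanning a
# south-to-north gradient, four spring seasons. All downstream scripts read
# this file; change it (or the seed) and rerun 01..05 to regenerate
# everything under results/.
simulation:
  stations:
    - {station_id: KNOR, latitude: 45.0, longitude: -93.0, night_length: 10}
    - {station_id: KMID, latitude: 39.0, longitude: -84.0, night_length: 10}
    - {station_id: KSOU, latitude: 33.0, longitude: -90.0, night_length: 10}
  years: [2014, 2015, 2016, 2017]
  season: spring
model:
  n_rounds: 500
  max_train_rows: 60000
targets: [0.25, 0.5, 0.75]
grid: [0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5,
       0.55, 0.6, 0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95]
seed: 42
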