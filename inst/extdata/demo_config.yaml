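# Demonstration configuration: offline run on the packaged synthetic fixture.
# Replace `input.fixture_path` with `input.api` settings for a live endpoint.
input:
  fixture_path: synthetic_health_indicators.csv
preprocess:
  aggregate_labels: ["india", "all india", "total"]
  region_map_path: india_region_map.csv
analyze:
  k: 3
  seed: 42
  tests:
    - kind: paired
      column_a: phc_24x7_dlhs_3
      column_b: phc_24x7_dlhs_4
      label: "PHC 24x7 availability, DLHS-3 to DLHS-4"
interpret:
  alpha: 0.05
report:
  output_dir: healthpipe_output
  prefix: report
  title: "Synthetic Public Health Indicator Report"
log_level: INFO
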