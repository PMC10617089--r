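# Synthetic demo for the flora-assembly pipeline: a seeded birth-death
# flora with painted taxonomy, era-dependent element labels and a known
# endemic set. Run with:
#   run_pipeline(demo_config_file(), out_dir = "demo_out")
synthetic:
  seed: 20231
  n_tips: 300
  n_genera: 75
  n_families: 20
  birth: 0.06
  death: 0.02
  nonmono_fraction: 0.2
  crossover: 10
  steepness: 0.5
  widespread_fraction: 0.05
  endemic_fraction: 0.3
  n_counties: 50
  region_fraction: 0.4
bin_width: 5
trajectory_width: 10
endemic_threshold: 0.9
temperate_includes_type15: true
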