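# "Ailao-like" synthetic survey configuration: the generator defaults,
# written out for the CLI `simulate` subcommand. Values are overrides for
# gradient_sim_config(); omitted fields keep their documented defaults.
n_bands: 6
band_step: 200
base_elevation: 1800
slopes: [west, east]
n_species: [27, 33]
n_shared: 23
placement_mode: mde_null
detection_prob: 0.001
trap_nights_per_band: 2200
abundance_mean: 11.4
endemic_prob: 0.55
insectivore_prob: 0.43
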