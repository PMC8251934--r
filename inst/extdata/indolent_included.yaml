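# Calibrated preset: indolent-included pathway.
# onset_rate calibrated to the unscreened PC-death burden (753 per 10,000);
# indolent_fraction calibrated to total resections under annual screening
# (1278 per 10,000). Regenerate with data-raw/calibrate-presets.R.
onset_rate: 0.9909043
onset_shape: 5.0
indolent_fraction: 0.3609375
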