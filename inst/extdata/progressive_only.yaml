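# Calibrated preset: progressive-only pathway.
# onset_rate calibrated to the unscreened PC-death burden (751 per 10,000);
# regenerate with data-raw/calibrate-presets.R.
onset_rate: 0.9557598
onset_shape: 5.0
indolent_fraction: 0.0
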