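band,kappa
delta,0.4665
theta,0.4101
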