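{"label":"wheat_soryzae_A_synthetic","n_impulses":139,"source_duration":62,"n_fft":256,"sample_rate":44100}
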