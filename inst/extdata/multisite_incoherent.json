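{"k1": 0.05, "k1r": 1, "k2_0": 0.2, "s2": 1, "h2": 1, "k2_sat": 20, "k3_0": 0.05, "s3": 0.1, "h3": 1, "k3_sat": 0.0005, "x": 2}
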