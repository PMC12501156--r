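{"k1": 0.01, "k1r": 1, "k2": 0.2, "k3": 0.05, "aT": 0.1, "bT": 1, "e2": 15, "e3": 0.01}
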