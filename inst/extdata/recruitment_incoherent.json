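{"aT": 0.01, "aT_p": 0.01, "bT": 0.1, "bT_Tp": 0.1, "ap": 0.01, "ap_T": 0.1, "bp": 0.1, "bp_Tp": 0.01, "q3": 1, "q4": 0.01}
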