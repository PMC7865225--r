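{"a1": 0.3, "a2": 0.35, "a3": 0.35}
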