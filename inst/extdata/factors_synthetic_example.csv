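# synthetic illustrative odds ratios; supply study-derived values in practice
smoking,1.9
familiarity,2.2
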