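# source=synthetic example alt-allele frequencies (illustrative only, not measured population data)
rs_id,alt_freq
rs1061170,0.35
rs10490924,0.22
rs2227306,0.40
rs5749482,0.72
rs8135665,0.20
rs8017304,0.38
rs943080,0.50
rs13081855,0.10
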