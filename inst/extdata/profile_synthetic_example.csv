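rs1061170,CT
rs10490924,GT
rs2227306,CC
rs5749482,CG
rs8135665,CT
rs8017304,AG
rs943080,TT
rs13081855,GG
smoking,yes
familiarity,absent
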