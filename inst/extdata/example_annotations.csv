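formula,adduct,mz,fdr
C5H6O4,[M-H]-,129.0193,0.05
C2H7NO3S,[M-H]-,124.0074,0.05
C5H9NO4,[M-H]-,146.0459,0.10
C4H4O4,[M-H]-,115.0037,0.10
C5H4N4O,[M-H]-,135.0312,0.10
C6H9NO5,[M-H]-,174.0408,0.20
C18H34O2,[M-H]-,281.2486,0.05
C10H17N3O6S,[M-H]-,306.0765,0.10
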