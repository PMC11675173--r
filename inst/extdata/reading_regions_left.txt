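IFGtriang.L
IFGoperc.L
INS.L
FFG.L
SMG.L
ANG.L
HES.L
STG.L
MTG.L
ITG.L
TPOsup.L
ROL.L
THA.L
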