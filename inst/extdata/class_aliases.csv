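subclass,parent
PC[O],PC
PC[P],PC
PC[O+P],PC
LPC[O],LPC
LPC[P],LPC
LPC[O+P],LPC
PE[O],PE
PE[P],PE
PE[O+P],PE
LPE[P],LPE
LPE[O+P],LPE
TAG[O],TAG
SM[d],SM
SM[t],SM
SPH[d],SPH
Cer[d],Cer
HexCer[d],GlcCer
Hex2Cer[d],LacCer
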