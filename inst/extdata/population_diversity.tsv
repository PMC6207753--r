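population	ho	he	fis
PET	0.23	0.23	-0.014
SAL	0.17	0.17	0.009
ATA	0.17	0.17	0.025
HYR	0.15	0.15	0.000
HYC	0.20	0.19	-0.017
CAM	0.17	0.18	0.045
HMT	0.15	0.15	-0.016
HYB	0.17	0.17	0.009
HTU	0.15	0.15	0.012
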