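pop1	pop2	fst
CAM	ATA	0.13
HYC	ATA	0.09
HYC	CAM	0.08
HMT	ATA	0.16
HMT	CAM	0.15
HMT	HYC	0.10
PET	ATA	0.13
PET	CAM	0.07
PET	HYC	0.08
PET	HMT	0.13
HYR	ATA	0.11
HYR	CAM	0.15
HYR	HYC	0.10
HYR	HMT	0.17
HYR	PET	0.13
SAL	ATA	0.13
SAL	CAM	0.12
SAL	HYC	0.10
SAL	HMT	0.18
SAL	PET	0.12
SAL	HYR	0.15
HTU	ATA	0.14
HTU	CAM	0.12
HTU	HYC	0.11
HTU	HMT	0.18
HTU	PET	0.13
HTU	HYR	0.15
HTU	SAL	0.15
HYB	ATA	0.09
HYB	CAM	0.14
HYB	HYC	0.07
HYB	HMT	0.14
HYB	PET	0.13
HYB	HYR	0.08
HYB	SAL	0.13
HYB	HTU	0.12
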