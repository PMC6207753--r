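lake	population	area_m2	salinity_g_l	hydroperiod	predictability	propensity_for_sex	hatching_fraction_pct
Petrola	PET	1190000	18.68	1.00	1.00	8.3	44.2
Salobralejo	SAL	237000	6.3	1.00	1.00	8.3	76.8
Atalaya de los Ojicos	ATA	47000	17.53	0.93	0.75	7.0	42.5
Hoya Rasa	HYR	40000	35.17	0.87	0.66	5.2	60.1
Hoya Chica	HYC	32000	10.79	0.51	0.12	5.5	71.6
La Campana	CAM	29000	4.9	0.63	0.11	2.9	61.6
Hoya del Monte	HMT	15800	9.36	0.51	0.19	5.6	83.1
Hoya Yerba	HYB	1060	5.03	0.23	0.34	3.5	82.7
Hoya Turnera	HTU	130	3.06	0.07	0.70	6.7	68.2
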