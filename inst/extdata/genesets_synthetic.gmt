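YAPTAZ_TARGETS_22_SYNTHETIC	synthetic stand-in for the 22-gene YAP/TAZ core target cluster (true membership is configuration, not a constant)	CCN1	CCN2	AMOTL2	ANKRD1	AXL	CTGF	CYR61	THBS1	SERPINE1	DIAPH3	FOSL1	CAV1	CAV2	GADD45A	TEAD1	MYOF	ARHGAP29	DOCK5	FJX1	LATS2	NT5E	PTX3
CLDN	claudin-low marker quartet	CLDN3	CLDN4	CLDN7	CDH1
YAP_WWTR1	YAP and TAZ genes for the raw-sum expression score	YAP1	WWTR1
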