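sample_id	dose_gy	time_days	study
S0001	0	1	FX1
S0002	0	1	FX2
S0003	2	1	FX1
S0004	2	1	FX2
S0005	6	1	FX1
S0006	6	1	FX2
S0007	10	1	FX1
S0008	10	1	FX2
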