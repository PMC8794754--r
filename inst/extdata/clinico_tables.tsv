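target	gene	feature	row1	row2	a	b	c	d
t2	PFDN2	tumor_size_cm	<5	>=5	26	19	5	13
t3	GEMIN5	age_years	<60	>=60	15	7	16	25
t4	PFDN2	T_stage	T1/T2	T3/T4	10	2	21	30
t5	GEMIN5	T_stage	T1/T2	T3/T4	9	3	22	29
t6	PFDN2	TNM_stage	I/II	III/IV	16	5	15	27
t7	PFDN2	histological_grade	well/moderate	poor	8	2	23	30
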