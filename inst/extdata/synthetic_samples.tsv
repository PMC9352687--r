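sample_id	patient_id	role	group
POLY001_P1	POLY001	primary	polyclonal
POLY001_M1	POLY001	metastasis	polyclonal
POLY002_P1	POLY002	primary	polyclonal
POLY002_M1	POLY002	metastasis	polyclonal
MONO001_P1	MONO001	primary	monoclonal
MONO001_M1	MONO001	metastasis	monoclonal
MONO002_P1	MONO002	primary	monoclonal
MONO002_M1	MONO002	metastasis	monoclonal
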