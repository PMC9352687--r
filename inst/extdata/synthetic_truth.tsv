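sample_id	true_purity	true_ploidy	mode
POLY001_P1	0.788461	2.310277	polyclonal
POLY001_M1	0.747089	2.287938	polyclonal
POLY002_P1	0.789502	2.571972	polyclonal
POLY002_M1	0.829079	2.591673	polyclonal
MONO001_P1	0.573143	2.158361	monoclonal
MONO001_M1	0.735735	2.397500	monoclonal
MONO002_P1	0.773041	2.040192	monoclonal
MONO002_M1	0.764534	1.943750	monoclonal
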