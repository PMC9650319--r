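metabolite	gene	snp_id	effect_allele	beta_e2	se_e2	beta_e3	se_e3	beta_e4	se_e4	contrast1	chi2_1	p_1	contrast2	chi2_2	p_2	identified_in
TAG 56:5	BCL3	rs2965101	C	0.096	0.028	-0.002	0.015	-0.068	0.028	E2-E3	9.274	2.32E-03	E2-E4	16.786	4.18E-05	E2
TAG 56:5	BCL3	rs17728272	T	0.094	0.028	-0.009	0.015	-0.055	0.030	E2-E3	10.455	1.22E-03	E2-E4	13.404	2.51E-04	E2
Glutamic acid	APOC2, APOC4-APOC2	rs10421404	A	-0.271	0.079	0.029	0.039	0.026	0.064	E2-E3	11.653	6.41E-04	E2-E4	8.472	3.61E-03	E2
LPE 16:0	APOC2, APOC4-APOC2	rs7257468	T	-0.143	0.041	-0.027	0.019	0.046	0.029	E2-E3	6.760	9.32E-03	E2-E4	14.270	1.58E-04	E2
LPE 18:0	APOC2, APOC4-APOC2	rs7257468	T	-0.144	0.043	0.000	0.017	0.063	0.032	E2-E3	9.615	1.93E-03	E2-E4	14.890	1.14E-04	E2
LPE 20:4	APOC2, APOC4-APOC2	rs7257468	T	-0.131	0.036	-0.022	0.015	0.041	0.023	E2-E3	7.648	5.68E-03	E2-E4	15.999	6.34E-05	E2
Glutamic acid	CLPTM1	rs10413089	C	-0.271	0.079	0.030	0.039	0.026	0.064	E2-E3	11.670	6.35E-04	E2-E4	8.472	3.61E-03	E2
LPE 16:0	CLPTM1	rs3760627	C	-0.136	0.040	-0.027	0.019	0.047	0.029	E2-E3	5.995	1.43E-02	E2-E4	13.469	2.43E-04	E2
LPE 18:0	CLPTM1	rs3760627	C	-0.136	0.043	-0.001	0.017	0.063	0.032	E2-E3	8.648	3.27E-03	E2-E4	13.954	1.87E-04	E2
LPE 20:4	CLPTM1	rs3760627	C	-0.127	0.036	-0.021	0.015	0.040	0.023	E2-E3	7.366	6.65E-03	E2-E4	15.344	8.96E-05	E2
LPE 16:0	CLPTM1	rs2239375	C	-0.136	0.040	-0.027	0.019	0.040	0.029	E2-E3	6.020	1.41E-02	E2-E4	12.508	4.05E-04	E2
LPE 18:0	CLPTM1	rs2239375	C	-0.136	0.043	-0.001	0.017	0.062	0.032	E2-E3	8.583	3.39E-03	E2-E4	13.746	2.09E-04	E2
LPE 20:4	CLPTM1	rs2239375	C	-0.127	0.036	-0.020	0.015	0.034	0.023	E2-E3	7.459	6.31E-03	E2-E4	14.215	1.63E-04	E2
PC 38:6	CKM	rs123187	A	0.101	0.029	0.000	0.011	-0.029	0.021	E2-E3	10.509	1.19E-03	E2-E4	13.090	2.97E-04	E2
Dimethylglycine	CKM	rs16979759	G	0.813	0.196	-0.102	0.058	0.148	0.082	E2-E3	20.013	7.69E-06	E2-E4	9.778	1.77E-03	E2
PC 32:1	NECTIN2	rs8105340	C	0.035	0.084	-0.031	0.033	0.201	0.054	E4-E2	2.778	9.56E-02	E4-E3	13.499	2.39E-04	E4
PC 32:0	NECTIN2	rs8105340	C	0.040	0.039	-0.007	0.017	0.112	0.028	E4-E2	2.208	1.37E-01	E4-E3	13.316	2.63E-04	E4
PC 34:1	NECTIN2	rs8105340	C	0.022	0.028	-0.015	0.011	0.073	0.018	E4-E2	2.344	1.26E-01	E4-E3	18.237	1.95E-05	E4
Isocitrate	NECTIN2	rs519113	G	0.026	0.029	0.008	0.016	0.111	0.025	E4-E2	4.914	2.66E-02	E4-E3	11.833	5.82E-04	E4
Propionate	APOC1	rs1064725	G	0.321	0.251	-0.012	0.077	-0.711	0.189	E4-E2	10.803	1.01E-03	E4-E3	11.716	6.20E-04	E4
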