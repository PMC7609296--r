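gene	allele	rsid	contig	pos	ref	alt	func
CYP2C19	*2	rs4244285	chr10	1000	G	A	no_function
CYP2C19	*3	rs4986893	chr10	1100	G	A	no_function
CYP2C19	*4	rs28399504	chr10	1200	A	G	no_function
CYP2C19	*5	rs56337013	chr10	1300	C	T	no_function
CYP2C19	*6	rs72552267	chr10	1400	G	A	no_function
CYP2C19	*7	rs72558186	chr10	1500	T	A	no_function
CYP2C19	*8	rs41291556	chr10	1600	T	C	no_function
CYP2C19	*17	rs12248560	chr10	1700	C	T	increased
CYP2C9	*2	rs1799853	chr10	2000	C	T	decreased
CYP2C9	*3	rs1057910	chr10	2100	A	C	decreased
SLCO1B1	*1B	rs2306283	chr12	3000	A	G	normal
SLCO1B1	*5	rs4149056	chr12	3100	T	C	decreased
SLCO1B1	*17	rs4149015	chr12	3200	G	A	decreased
VKORC1	A	rs9923231	chr16	4000	G	A	profile
ALDH2	A	rs671	chr12	5000	G	A	profile
ADH1B	rs1229984_T	rs1229984	chr4	6000	C	T	profile
ADH1B	rs2066702_A	rs2066702	chr4	6100	G	A	profile
CYP1A2	C	rs762551	chr15	7000	A	C	profile
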