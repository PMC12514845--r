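# SYNTHETIC reference statistics for HalBS scoring.
# Quartiles constructed from published per-category medians/ranges and
# observation counts, NOT derived from a structure corpus. For research
# use, calibrate on your own corpus (see ?calibrate).
halogen	acceptor_class	parameter	n	mean	median	q1	q3	mad
F	O-C	distance	4381	3.5	3.5	3.35	3.65	0.075
F	O-C	theta1	4381	132	132	116	148	8
F	O-C	theta2	4381	105	105	93	117	6
CL	O-C	distance	456	3.5	3.5	3.35	3.65	0.075
CL	O-C	theta1	456	143	143	128	158	7.5
CL	O-C	theta2	456	105	105	93	117	6
BR	O-C	distance	2479	3.45	3.45	3.27	3.6300000000000003	0.09
BR	O-C	theta1	2479	154	154	141	167	6.5
BR	O-C	theta2	2479	108	108	96	120	6
I	O-C	distance	156	3.4	3.4	3.15	3.65	0.125
I	O-C	theta1	156	169	169	160	178	4.5
I	O-C	theta2	156	117	117	105	129	6
F	S-C	distance	554	3.5	3.5	3.35	3.65	0.075
F	S-C	theta1	554	132	132	116	148	8
F	S-C	theta2	554	105	105	93	117	6
CL	S-C	distance	80	3.5	3.5	3.35	3.65	0.075
CL	S-C	theta1	80	143	143	128	158	7.5
CL	S-C	theta2	80	105	105	93	117	6
BR	S-C	distance	312	3.45	3.45	3.27	3.6300000000000003	0.09
BR	S-C	theta1	312	154	154	141	167	6.5
BR	S-C	theta2	312	108	108	96	120	6
I	S-C	distance	5	3.4	3.4	3.15	3.65	0.125
I	S-C	theta1	5	169	169	160	178	4.5
I	S-C	theta2	5	117	117	105	129	6
F	Phe	distance	2097	4.8	4.8	4.35	5.25	0.225
F	Phe	theta1	2097	130	130	115	145	7.5
CL	Phe	distance	167	4.8	4.8	4.35	5.25	0.225
CL	Phe	theta1	167	130	130	115	145	7.5
BR	Phe	distance	1100	4.8	4.8	4.35	5.25	0.225
BR	Phe	theta1	1100	130	130	115	145	7.5
I	Phe	distance	49	5.1	5.1	4.6499999999999995	5.55	0.225
I	Phe	theta1	49	130	130	115	145	7.5
F	Tyr	distance	1328	4.8	4.8	4.35	5.25	0.225
F	Tyr	theta1	1328	130	130	115	145	7.5
CL	Tyr	distance	102	4.8	4.8	4.35	5.25	0.225
CL	Tyr	theta1	102	130	130	115	145	7.5
BR	Tyr	distance	895	4.8	4.8	4.35	5.25	0.225
BR	Tyr	theta1	895	130	130	115	145	7.5
I	Tyr	distance	14	5.1	5.1	4.6499999999999995	5.55	0.225
I	Tyr	theta1	14	130	130	115	145	7.5
F	His	distance	1135	4.8	4.8	4.35	5.25	0.225
F	His	theta1	1135	125	125	110	140	7.5
CL	His	distance	55	4.8	4.8	4.35	5.25	0.225
CL	His	theta1	55	115	115	100	130	7.5
BR	His	distance	257	4.8	4.8	4.35	5.25	0.225
BR	His	theta1	257	115	115	100	130	7.5
I	His	distance	9	5.1	5.1	4.6499999999999995	5.55	0.225
I	His	theta1	9	125	125	110	140	7.5
F	Trp	distance	539	4.8	4.8	4.35	5.25	0.225
F	Trp	theta1	539	125	125	110	140	7.5
CL	Trp	distance	121	4.8	4.8	4.35	5.25	0.225
CL	Trp	theta1	121	115	115	100	130	7.5
BR	Trp	distance	225	4.8	4.8	4.35	5.25	0.225
BR	Trp	theta1	225	115	115	100	130	7.5

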