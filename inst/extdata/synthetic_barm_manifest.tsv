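sample_id	station	date	depth_m	o2_detected	o2_mL_per_L	filter_um	prefilter_um	dataset
RDX01	TF0271	2014-10-18	80	TRUE	0.7	0.2		Redoxcline 2014
RDX02	TF0271	2014-10-18	200	FALSE		0.2		Redoxcline 2014
RDX03	TF0271	2014-10-26	60	TRUE	1.6	3		Redoxcline 2014
RDX04	TF0271	2014-10-26	60	TRUE	1.6	0.2	3	Redoxcline 2014
RDX05	TF0271	2014-10-26	117	TRUE	0.5	3		Redoxcline 2014
RDX06	TF0271	2014-10-26	117	TRUE	0.5	0.2	3	Redoxcline 2014
RDX07	TF0271	2014-10-26	140	FALSE		3		Redoxcline 2014
RDX08	TF0271	2014-10-26	140	FALSE		0.2	3	Redoxcline 2014
RDX09	TF0271	2014-10-26	200	FALSE		3		Redoxcline 2014
RDX10	TF0271	2014-10-26	200	FALSE		0.2	3	Redoxcline 2014
RDX11	BoknisEck	2014-09-23	15	TRUE	4.5	3		Redoxcline 2014
RDX12	BoknisEck	2014-09-23	15	TRUE	4.5	0.2	3	Redoxcline 2014
RDX13	BoknisEck	2014-09-23	25	FALSE		3		Redoxcline 2014
RDX14	BoknisEck	2014-09-23	25	FALSE		0.2	3	Redoxcline 2014
TRN01	AT1	2014-06-04	2	TRUE	5	0.2		Transect 2014
TRN02	AT1	2014-06-04	30	TRUE	4.5	0.2		Transect 2014
TRN03	AT1	2014-06-04	106	TRUE	4.9	0.2		Transect 2014
TRN04	AT3	2014-06-05	2	TRUE	6.4	0.2		Transect 2014
TRN05	AT3	2014-06-05	30	TRUE	4	0.2		Transect 2014
TRN06	AT3	2014-06-05	117	TRUE	0.9	0.2		Transect 2014
TRN07	AT4	2014-06-06	2	TRUE	5	0.2		Transect 2014
TRN08	AT4	2014-06-06	30	TRUE	4.7	0.2		Transect 2014
TRN09	AT4	2014-06-06	230	TRUE	7.6	0.2		Transect 2014
TRN10	MO3	2014-06-07	2	TRUE	7.3	0.2		Transect 2014
TRN11	MO3	2014-06-07	30	TRUE	4.6	0.2		Transect 2014
TRN12	MO3	2014-06-07	90	TRUE	0.8	0.2		Transect 2014
TRN13	MO6	2014-06-08	2	TRUE	4.1	0.2		Transect 2014
TRN14	MO6	2014-06-08	30	TRUE	4.4	0.2		Transect 2014
TRN15	MO6	2014-06-08	80	TRUE	6.9	0.2		Transect 2014
TRN16	MO7	2014-06-09	2	TRUE	6.6	0.2		Transect 2014
TRN17	MO7	2014-06-09	30	TRUE	3.4	0.2		Transect 2014
TRN18	MO7	2014-06-09	182	TRUE	7.4	0.2		Transect 2014
TRN19	S6	2014-06-10	2	TRUE	7.1	0.2		Transect 2014
TRN20	S6	2014-06-10	30	TRUE	3.1	0.2		Transect 2014
TRN21	S6	2014-06-10	200	TRUE	7.6	0.2		Transect 2014
TRN22	S7	2014-06-11	2	TRUE	5.9	0.2		Transect 2014
TRN23	S7	2014-06-11	30	TRUE	5.2	0.2		Transect 2014
TRN24	S7	2014-06-11	76.5	TRUE	0.7	0.2		Transect 2014
TRN25	S10	2014-06-12	2	TRUE	3.9	0.2		Transect 2014
TRN26	S10	2014-06-12	30	TRUE	5.6	0.2		Transect 2014
TRN27	S10	2014-06-12	134	TRUE	2.6	0.2		Transect 2014
TRN28	TF245	2014-06-13	2	TRUE	5.8	0.2		Transect 2014
TRN29	TF245	2014-06-13	30	TRUE	6.4	0.2		Transect 2014
TRN30	TF245	2014-06-13	87.5	TRUE	1	0.2		Transect 2014
LMO01	LMO	2012-03-14	2	TRUE	6	0.2	3	LMO 2012
LMO02	LMO	2012-03-21	2	TRUE	5.1	0.2	3	LMO 2012
LMO03	LMO	2012-03-29	2	TRUE	6.2	0.2	3	LMO 2012
LMO04	LMO	2012-04-06	2	TRUE	5.4	0.2	3	LMO 2012
LMO05	LMO	2012-04-14	2	TRUE	5.2	0.2	3	LMO 2012
LMO06	LMO	2012-04-22	2	TRUE	4.1	0.2	3	LMO 2012
LMO07	LMO	2012-04-29	2	TRUE	7	0.2	3	LMO 2012
LMO08	LMO	2012-05-07	2	TRUE	5.1	0.2	3	LMO 2012
LMO09	LMO	2012-05-15	2	TRUE	4.1	0.2	3	LMO 2012
LMO10	LMO	2012-05-23	2	TRUE	6.4	0.2	3	LMO 2012
LMO11	LMO	2012-05-31	2	TRUE	5.2	0.2	3	LMO 2012
LMO12	LMO	2012-06-07	2	TRUE	6.8	0.2	3	LMO 2012
LMO13	LMO	2012-06-15	2	TRUE	7.3	0.2	3	LMO 2012
LMO14	LMO	2012-06-23	2	TRUE	5.9	0.2	3	LMO 2012
LMO15	LMO	2012-07-01	2	TRUE	5	0.2	3	LMO 2012
LMO16	LMO	2012-07-09	2	TRUE	5.1	0.2	3	LMO 2012
LMO17	LMO	2012-07-16	2	TRUE	4.2	0.2	3	LMO 2012
LMO18	LMO	2012-07-24	2	TRUE	7.3	0.2	3	LMO 2012
LMO19	LMO	2012-08-01	2	TRUE	7.3	0.2	3	LMO 2012
LMO20	LMO	2012-08-09	2	TRUE	6.2	0.2	3	LMO 2012
LMO21	LMO	2012-08-17	2	TRUE	5.5	0.2	3	LMO 2012
LMO22	LMO	2012-08-24	2	TRUE	4.6	0.2	3	LMO 2012
LMO23	LMO	2012-09-01	2	TRUE	5.1	0.2	3	LMO 2012
LMO24	LMO	2012-09-09	2	TRUE	5.7	0.2	3	LMO 2012
LMO25	LMO	2012-09-17	2	TRUE	6.4	0.2	3	LMO 2012
LMO26	LMO	2012-09-25	2	TRUE	4.9	0.2	3	LMO 2012
LMO27	LMO	2012-10-02	2	TRUE	4.4	0.2	3	LMO 2012
LMO28	LMO	2012-10-10	2	TRUE	6.7	0.2	3	LMO 2012
LMO29	LMO	2012-10-18	2	TRUE	6.5	0.2	3	LMO 2012
LMO30	LMO	2012-10-26	2	TRUE	6	0.2	3	LMO 2012
LMO31	LMO	2012-11-03	2	TRUE	5.6	0.2	3	LMO 2012
LMO32	LMO	2012-11-10	2	TRUE	6.5	0.2	3	LMO 2012
LMO33	LMO	2012-11-18	2	TRUE	5.6	0.2	3	LMO 2012
LMO34	LMO	2012-11-26	2	TRUE	6.2	0.2	3	LMO 2012
LMO35	LMO	2012-12-04	2	TRUE	4.6	0.2	3	LMO 2012
LMO36	LMO	2012-12-12	2	TRUE	6.1	0.2	3	LMO 2012
LMO37	LMO	2012-12-20	2	TRUE	4.5	0.2	3	LMO 2012
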