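line	query	cum_relevant	cum_retrieved	sensitivity_full_printed	sensitivity_internal_printed	precision_printed
1	off label*.af.	3150	3577	77.45	81.90	88.06
2	(off adj1 label).mp.	3152	3581	77.50	81.96	88.02
3	(drug adj2 label adj2 us*).af.	3153	3617	77.53	81.98	87.17
4	unlicense*.af.	3279	4320	80.62	85.26	75.90
5	unapprove*.af.	3445	4635	84.71	89.57	74.33
6	(label adj3 indication*).af.	3450	4667	84.83	89.70	73.92
7	off li?en?e*.af.	3509	4742	86.28	91.24	74.00
8	((no* licen?ed for adj3 use*) not now licen?ed).af.	3560	4825	87.53	92.56	73.78
9	((inappropriate us* and indication) not (antibiotic* or antimicrobial)).af.	3609	4964	88.74	93.84	72.70
10	((appropriate* adj3 prescri*) and indication).af.	3648	5081	89.70	94.85	71.80
11	(outside adj3 licen?e*).af.	3665	5110	90.12	95.29	71.72
12	unlabel* us*.af.	3692	5140	90.78	96.00	71.83
13	labeled indication*.af.	3703	5169	91.05	96.28	71.64
14	(inappropriate indication*).af.	3719	5294	91.44	96.70	70.25
15	nonapprove*.af.	3737	5337	91.89	97.17	70.02
16	registered indication*.af.	3752	5367	92.25	97.56	69.91
17	offlabel*.af.	3757	5372	92.38	97.69	69.94
18	(out* adj4 licen?ed indication*).af.	3759	5376	92.43	97.74	69.92
19	(unlabel* adj3 indication*).af.	3767	5384	92.62	97.95	69.97
20	non fda approve*.af.	3780	5411	92.94	98.28	69.86
21	((no* licen?ed for adj3 indication*) not now licen?ed).af.	3793	5425	93.26	98.62	69.92
22	(appropriate indication adj3 us*).af.	3796	5432	93.34	98.70	69.88
23	(be???d* adj2 licen?ed indication*).af.	3799	5436	93.41	98.78	69.89
24	(us* without adj2 indication*).af.	3804	5445	93.53	98.91	69.86
25	(prescri* outside adj4 guideline*).af.	3808	5450	93.63	99.01	69.87
26	(out of label).af.	3810	5466	93.68	99.06	69.70
27	(improper adj1 indication*).af.	3812	5472	93.73	99.12	69.66
28	(inappropriate adj5 indication adj2 us*).af.	3814	5475	93.78	99.17	69.66
29	no* appropriate indication*.af.	3815	5482	93.80	99.19	69.59
30	(non evidence base* us*).af.	3818	5487	93.88	99.27	69.58
31	without proper indication*.af.	3821	5498	93.95	99.35	69.50
32	(or/1-31) or (drug* without adj2 indication*).af.	3822	5501	93.98	99.38	69.48
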