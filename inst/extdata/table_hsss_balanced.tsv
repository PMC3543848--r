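line	query	cum_relevant	cum_retrieved	sensitivity_full_printed	sensitivity_internal_printed	precision_printed
1	off label*.af.	3150	3577	77.45	81.90	88.06
2	(unlicensed not (unlicensed aide* or unlicensed assist* or unlicensed car* or (unlicensed adj2 heal*) or unlicensed home* or (killer adj2 cell*) or (unlicensed adj2 individual*) or (unlicensed adj2 nurs*) or (unlicensed adj4 practi*) or (unlicensed adj2 physician*) or (unlicensed adj2 operat*) or (unlicensed adj2 person*) or unlicensed profession* or unlicensed rid* or (unlicensed adj3 staff*) or unlicensed therapist* or (unlicensed adj5 vaccine*) or unlicensed vendor* or (unlicensed adj2 work*) or (unlicensed adj2 employe*) or device* or dentist* or driver or driving or herbal or medical graduate* or motor* or pesticide* or premis* or prostitute* or restaurant* or veterinary or worker*)).af.	3272	3858	80.45	85.08	84.81
3	(unapprove* adj2 us*).af.	3331	3947	81.90	86.61	84.39
4	(unapprove* adj5 indication*).af.	3367	3986	82.79	87.55	84.47
5	off li?en?e.af.	3425	4053	84.21	89.05	84.51
6	((no* licen?ed for adj3 use*) not now licen?ed).af.	3476	4136	85.47	90.38	84.04
7	(unapprove* adj2 drug*).af.	3493	4181	85.89	90.82	83.54
8	(outside adj3 licen?e*).af.	3511	4211	86.33	91.29	83.38
9	unlabel* us*.af.	3538	4241	86.99	91.99	83.42
10	labeled indication*.af.	3549	4270	87.26	92.28	83.11
11	nonapprove*.af.	3569	4317	87.76	92.80	82.67
12	registered indication*.af.	3585	4348	88.15	93.21	82.45
13	offlabel*.af.	3590	4353	88.27	93.34	82.47
14	(unlabel* adj3 indication*).af.	3598	4361	88.47	93.55	82.50
15	non fda approve*.af.	3611	4388	88.79	93.89	82.29
16	((no* licen?ed for adj3 indication*) not now licen?ed).af.	3624	4402	89.11	94.23	82.33
17	(appropriate indication adj3 us*).af.	3630	4413	89.25	94.38	82.26
18	(be???d* adj2 licen?ed indication*).af.	3633	4417	89.33	94.46	82.25
19	(us* without adj2 indication*).af.	3638	4428	89.45	94.59	82.16
20	(prescri* outside adj4 guideline*).af.	3643	4434	89.57	94.72	82.16
21	(inappropriate adj5 indication adj2 us*).af.	3647	4441	89.67	94.83	82.12
22	(non evidence base* us*).af.	3650	4446	89.75	94.90	82.10
23	(or/1-22) not (stent* or veterinar*).af.	3635	4158	89.38	94.51	87.42
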