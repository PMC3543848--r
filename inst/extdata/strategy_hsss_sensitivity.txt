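1	off label*.af.
2	(off adj1 label).mp.
3	(drug adj2 label adj2 us*).af.
4	unlicense*.af.
5	unapprove*.af.
6	(label adj3 indication*).af.
7	off li?en?e*.af.
8	((no* licen?ed for adj3 use*) not now licen?ed).af.
9	((inappropriate us* and indication) not (antibiotic* or antimicrobial)).af.
10	((appropriate* adj3 prescri*) and indication).af.
11	(outside adj3 licen?e*).af.
12	unlabel* us*.af.
13	labeled indication*.af.
14	(inappropriate indication*).af.
15	nonapprove*.af.
16	registered indication*.af.
17	offlabel*.af.
18	(out* adj4 licen?ed indication*).af.
19	(unlabel* adj3 indication*).af.
20	non fda approve*.af.
21	((no* licen?ed for adj3 indication*) not now licen?ed).af.
22	(appropriate indication adj3 us*).af.
23	(be???d* adj2 licen?ed indication*).af.
24	(us* without adj2 indication*).af.
25	(prescri* outside adj4 guideline*).af.
26	(out of label).af.
27	(improper adj1 indication*).af.
28	(inappropriate adj5 indication adj2 us*).af.
29	no* appropriate indication*.af.
30	(non evidence base* us*).af.
31	without proper indication*.af.
32	(or/1-31) or (drug* without adj2 indication*).af.
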