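1	off label*.af.
2	(unlicensed not (unlicensed aide* or unlicensed assist* or unlicensed car* or (unlicensed adj2 heal*) or unlicensed home* or (killer adj2 cell*) or (unlicensed adj2 individual*) or (unlicensed adj2 nurs*) or (unlicensed adj4 practi*) or (unlicensed adj2 physician*) or (unlicensed adj2 operat*) or (unlicensed adj2 person*) or unlicensed profession* or unlicensed rid* or (unlicensed adj3 staff*) or unlicensed therapist* or (unlicensed adj5 vaccine*) or unlicensed vendor* or (unlicensed adj2 work*) or (unlicensed adj2 employe*) or device* or dentist* or driver or driving or herbal or medical graduate* or motor* or pesticide* or premis* or prostitute* or restaurant* or veterinary or worker*)).af.
3	(unapprove* adj2 us*).af.
4	(unapprove* adj5 indication*).af.
5	off li?en?e.af.
6	((no* licen?ed for adj3 use*) not now licen?ed).af.
7	(unapprove* adj2 drug*).af.
8	(outside adj3 licen?e*).af.
9	unlabel* us*.af.
10	labeled indication*.af.
11	nonapprove*.af.
12	registered indication*.af.
13	offlabel*.af.
14	(unlabel* adj3 indication*).af.
15	non fda approve*.af.
16	((no* licen?ed for adj3 indication*) not now licen?ed).af.
17	(appropriate indication adj3 us*).af.
18	(be???d* adj2 licen?ed indication*).af.
19	(us* without adj2 indication*).af.
20	(prescri* outside adj4 guideline*).af.
21	(inappropriate adj5 indication adj2 us*).af.
22	(non evidence base* us*).af.
23	(or/1-22) not (stent* or veterinar*).af.
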