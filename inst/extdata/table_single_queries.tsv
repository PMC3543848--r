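query	n_relevant_retrieved	n_retrieved	sensitivity_full_printed	sensitivity_internal_printed	precision_printed	nnr_printed
off label*.af.	3150	3577	77.5	81.9	88.1	1.1
(off adj2 label*).mp.	3131	3589	77.0	81.4	87.2	1.1
(off adj1 label*).mp.	3130	3567	77.0	81.4	87.7	1.1
off label*.mp.	3128	3555	76.9	81.3	88.0	1.1
off label.af.	3119	3542	76.7	81.1	88.1	1.1
(off adj1 label).mp.	3119	3544	76.7	81.1	88.0	1.1
(off adj2 label).mp.	3119	3547	76.7	81.1	87.9	1.1
off label.mp.	3117	3540	76.6	81.0	88.1	1.1
"off label*".ab,ti.	2306	2696	56.7	60.0	85.5	1.2
off label.ab,ti.	2293	2679	56.4	59.6	85.6	1.2
"off label*".ab.	1882	2224	46.3	48.9	84.6	1.2
off label.ab.	1870	2208	46.0	48.6	84.7	1.2
(drug adj2 label adj2 us*).af.	1587	1719	39.0	41.3	92.3	1.1
(drug adj1 label adj1 us*).af.	1581	1710	38.9	41.1	92.5	1.1
"off label drug us*".af.	1580	1677	38.8	41.1	94.2	1.1
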