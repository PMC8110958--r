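category	key1	key2	value
stack	CG	CG	-3.26
stack	CG	GC	-2.36
stack	CG	GU	-2.1
stack	CG	UG	-2.1
stack	CG	AU	-2.11
stack	CG	UA	-2.08
stack	GC	CG	-3.42
stack	GC	GC	-3.26
stack	GC	GU	-2.1
stack	GC	UG	-2.1
stack	GC	AU	-2.35
stack	GC	UA	-2.24
stack	GU	CG	-2.1
stack	GU	GC	-2.1
stack	GU	GU	-0.5
stack	GU	UG	-0.5
stack	GU	AU	-1.2
stack	GU	UA	-1.2
stack	UG	CG	-2.1
stack	UG	GC	-2.1
stack	UG	GU	-0.5
stack	UG	UG	-0.5
stack	UG	AU	-1.2
stack	UG	UA	-1.2
stack	AU	CG	-2.24
stack	AU	GC	-2.08
stack	AU	GU	-1.2
stack	AU	UG	-1.2
stack	AU	AU	-0.93
stack	AU	UA	-1.1
stack	UA	CG	-2.35
stack	UA	GC	-2.11
stack	UA	GU	-1.2
stack	UA	UG	-1.2
stack	UA	AU	-1.33
stack	UA	UA	-0.93
hairpin	1	NA	1e+09
hairpin	2	NA	1e+09
hairpin	3	NA	5.4
hairpin	4	NA	5.6
hairpin	5	NA	5.7
hairpin	6	NA	5.4
hairpin	7	NA	6
hairpin	8	NA	5.5
hairpin	9	NA	6.4
hairpin	10	NA	6.5136
hairpin	11	NA	6.6163
hairpin	12	NA	6.7101
hairpin	13	NA	6.7964
hairpin	14	NA	6.8763
hairpin	15	NA	6.9507
hairpin	16	NA	7.0202
hairpin	17	NA	7.0856
hairpin	18	NA	7.1472
hairpin	19	NA	7.2055
hairpin	20	NA	7.2608
hairpin	21	NA	7.3134
hairpin	22	NA	7.3635
hairpin	23	NA	7.4115
hairpin	24	NA	7.4573
hairpin	25	NA	7.5013
hairpin	26	NA	7.5436
hairpin	27	NA	7.5843
hairpin	28	NA	7.6235
hairpin	29	NA	7.6613
hairpin	30	NA	7.6979
bulge	1	NA	3.8
bulge	2	NA	2.8
bulge	3	NA	3.2
bulge	4	NA	3.6
bulge	5	NA	4
bulge	6	NA	4.4
bulge	7	NA	4.5662
bulge	8	NA	4.7101
bulge	9	NA	4.8371
bulge	10	NA	4.9507
bulge	11	NA	5.0534
bulge	12	NA	5.1472
bulge	13	NA	5.2335
bulge	14	NA	5.3134
bulge	15	NA	5.3878
bulge	16	NA	5.4573
bulge	17	NA	5.5227
bulge	18	NA	5.5843
bulge	19	NA	5.6426
bulge	20	NA	5.6979
bulge	21	NA	5.7505
bulge	22	NA	5.8006
bulge	23	NA	5.8485
bulge	24	NA	5.8944
bulge	25	NA	5.9384
bulge	26	NA	5.9807
bulge	27	NA	6.0214
bulge	28	NA	6.0606
bulge	29	NA	6.0984
bulge	30	NA	6.135
internal	1	NA	1e+09
internal	2	NA	1.5
internal	3	NA	1.6
internal	4	NA	1.7
internal	5	NA	1.8
internal	6	NA	2
internal	7	NA	2.1662
internal	8	NA	2.3101
internal	9	NA	2.4371
internal	10	NA	2.5507
internal	11	NA	2.6534
internal	12	NA	2.7472
internal	13	NA	2.8335
internal	14	NA	2.9134
internal	15	NA	2.9878
internal	16	NA	3.0573
internal	17	NA	3.1227
internal	18	NA	3.1843
internal	19	NA	3.2426
internal	20	NA	3.2979
internal	21	NA	3.3505
internal	22	NA	3.4006
internal	23	NA	3.4485
internal	24	NA	3.4944
internal	25	NA	3.5384
internal	26	NA	3.5807
internal	27	NA	3.6214
internal	28	NA	3.6606
internal	29	NA	3.6984
internal	30	NA	3.735
misc	asym	NA	0.6
misc	asym_max	NA	3
misc	ml_close	NA	3.4
misc	ml_branch	NA	0.4
misc	ml_unpaired	NA	0
misc	lxc	NA	1.078
misc	maxloop	NA	30
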