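treatment	acetate_mM	formate_mM	doubling_time_h	sd	n
0 mM	0	0	1.322	0.047	6
0.5 mM Ac	0.5	0	1.516	0.052	6
1 mM Ac	1	0	1.452	0.034	6
5 mM Ac	5	0	1.929	0.037	6
10 mM Ac	10	0	1.562	0.028	6
0.5 mM Fo	0	0.5	1.474	0.042	6
1 mM Fo	0	1	1.718	0.078	6
5 mM Fo	0	5	1.561	0.034	6
10 mM Fo	0	10	1.521	0.034	6
10 mM Ac + 10 mM Fo	10	10	1.734	0.05	6
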