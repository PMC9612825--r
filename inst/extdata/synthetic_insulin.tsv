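time_min	fold_change	sd
3	1.92326034008466	0.225
6	1.57984659012218	0.23256560919885
10	1.82111802051144	0.24544780074331
15	2.43619854484395	0.319763732731359
60	2.97887325901365	0.45
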