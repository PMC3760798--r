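# Synthetic reconstruction of a TNFa-induced IKK activity profile
# basal=0.01
time_min	ikk_activity
0	0.01
5	1
10	0.75
20	0.3
30	0.12
45	0.06
60	0.035
90	0.022
120	0.017
240	0.016
360	0.016
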