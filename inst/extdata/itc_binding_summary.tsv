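# Published ITC summary for RelA-TA2 peptides binding the CBP TAZ1 domain
# at 25 C (298.15 K). Columns: construct label, NaCl (mM), Kd (nM) with s.d.,
# dH (kcal/mol) with s.d., TdS (kcal/mol) with s.d. NB = no binding.
label	salt_mM	kd_nM	kd_err	dh_kcal	dh_err	tds_kcal	tds_err
425-508 wt	50	57.0	3.2	-5.9	0.1	3.9	0.1
425-508 S467D	50	41.2	0.3	-6.5	0.1	3.5	0.1
425-508 wt	150	244.4	11.3	-7.2	0.1	1.8	0.1
441-508 wt	150	386.8	33.4	-8.3	0.4	0.5	0.5
425-508 L449A	150	1604.5	194.1	-5.4	0.3	2.5	0.3
425-508 L465A	150	1706.8	434.5	-2.4	0.3	5.5	0.5
425-508 F473A	150	NB	NB	NB	NB	NB	NB
425-508 S467D	150	173.9	7.2	-7.8	0.1	1.4	0.1
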