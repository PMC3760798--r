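# Default parameter set for the IkB-NF-kB feedback module.
# Reconstruction in the style of the cited precursor model family
# (provenance precursor_default); apply adapt_parameters() before use.
key	value
total_nfkb	0.1
nfkb_scale	1
kmrna_scale	1
volume_ratio	3.3
transcription.a.k_basal	2e-05
transcription.a.k_induced_max	0.036
transcription.a.K_half	0.6
transcription.a.h	2
transcription.b.k_basal	1e-05
transcription.b.k_induced_max	0
transcription.b.K_half	0.6
transcription.b.h	2
transcription.e.k_basal	5e-06
transcription.e.k_induced_max	0.007
transcription.e.K_half	0.6
transcription.e.h	2
translation.a	0.24
translation.b	0.24
translation.e	0.24
mrna_degradation.a	0.029
mrna_degradation.b	0.0077
mrna_degradation.e	0.017
mrna_degradation_factor	NA
deg_free_basal.a	0.12
deg_free_basal.b	0.18
deg_free_basal.e	0.18
deg_free_ikk.a	0.18
deg_free_ikk.b	0.06
deg_free_ikk.e	0.09
deg_bound_basal.a	6e-05
deg_bound_basal.b	6e-05
deg_bound_basal.e	6e-05
deg_bound_ikk.a	0.36
deg_bound_ikk.b	0.12
deg_bound_ikk.e	0.18
assoc.a	30
assoc.b	30
assoc.e	30
dissoc.a	0.003
dissoc.b	0.003
dissoc.e	0.003
imp_nfkb	5.4
exp_nfkb	0.0048
imp_ikb.a	0.36
imp_ikb.b	0.009
imp_ikb.e	0.09
exp_ikb.a	0.012
exp_ikb.b	0.012
exp_ikb.e	0.012
exp_complex.a	0.84
exp_complex.b	0.42
exp_complex.e	0.42
adapted	FALSE
provenance	precursor_default
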