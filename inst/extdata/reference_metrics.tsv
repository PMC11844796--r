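model	class	sensitivity	specificity	balanced_accuracy
maximal_brain_cognition	bvFTD	88.88	91.46	90.17
maximal_brain_cognition	svPPA	93.56	97.15	95.36
maximal_brain_cognition	nfvPPA	84.19	94.65	89.42
maximal_cognition	bvFTD	87.34	91.65	89.50
maximal_cognition	svPPA	84.92	94.53	89.73
maximal_cognition	nfvPPA	85.43	92.74	89.08
maximal_brain	bvFTD	63.50	76.28	69.89
maximal_brain	svPPA	93.76	94.92	94.34
maximal_brain	nfvPPA	50.71	82.47	66.59
maximal_longitudinal	bvFTD	85.71	95.65	90.68
maximal_longitudinal	svPPA	92.31	95.83	94.07
maximal_longitudinal	nfvPPA	90.00	92.59	91.30
minimal_brain_cognition	bvFTD	84.35	86.38	85.37
minimal_brain_cognition	svPPA	87.50	93.34	90.42
minimal_brain_cognition	nfvPPA	76.17	93.51	84.84
minimal_bc_maximal_sample	bvFTD	90.66	86.93	88.80
minimal_bc_maximal_sample	svPPA	92.00	94.34	93.17
minimal_bc_maximal_sample	nfvPPA	76.14	98.26	87.20
minimal_cognition	bvFTD	84.82	80.91	82.87
minimal_cognition	svPPA	70.19	89.07	79.63
minimal_cognition	nfvPPA	61.13	91.52	76.33
minimal_cog_maximal_sample	bvFTD	88.69	81.22	84.95
minimal_cog_maximal_sample	svPPA	69.84	89.43	79.64
minimal_cog_maximal_sample	nfvPPA	65.90	92.84	79.37
minimal_longitudinal	bvFTD	81.77	94.43	88.10
minimal_longitudinal	svPPA	92.85	90.27	91.56
minimal_longitudinal	nfvPPA	87.00	94.38	90.69
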