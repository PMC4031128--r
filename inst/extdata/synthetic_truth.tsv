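#param	n_pos	9
#param	n_neg	7
#param	p	40
#param	n_disc	5
#param	effect	2
#param	sigma	1
#param	depth_mean	600
#param	depth_cv	0.34
#param	richness_bonus	8
#param	seed	2024
otu_id	effect
OTU_0003	2
OTU_0006	-2
OTU_0007	2
OTU_0014	-2
OTU_0030	2
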