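# CLOVER enrichment p-values of known TF binding motifs in the CRM sets
# where Hb (resp. Kr) is preferred as activator (act) vs repressor (rep),
# against all D. melanogaster intergenic regions.  Empty cell = not tested.
tf	hb_act	hb_rep	kr_act	kr_rep
Abd-B	0.0	0.0	0.0	0.0
Deaf1			0.079	0.005
His2B	0.048	0.0	0.0	0.058
Hsf	0.085	0.008	0.0	0.231
Kr	0.0	0.0	0.0	0.0
Bcd	0.0	0.0	0.0	0.0
Br-Z4			0.821	0.006
Cad	0.002	0.0	0.0	0.0
Hb	0.032	0.0	0.0	0.0
Kni	0.032	0.01	0.702	0.0
Tll	0.003	0.0	0.0	0.0
Ttk	0.02	0.0	0.003	0.0
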