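name	chrom	start	end	flank
PPARG	3	12328984	12475855	500000
ABCC8	11	17414432	17498449	500000
GLP1R	6	39016557	39055520	500000
SLC5A2	16	31494323	31502181	500000
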