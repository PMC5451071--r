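locus,allele,frequency
DRB1,*01:01,0.092
DRB1,*01:02,0.014
DRB1,*03:01,0.108
DRB1,*04:01,0.083
DRB1,*04:04,0.035
DRB1,*04:07,0.010
DRB1,*07:01,0.121
DRB1,*10:01,0.012
DRB1,*11:01,0.065
DRB1,*12:01,0.019
DRB1,*13:01,0.058
DRB1,*13:02,0.042
DRB1,*14:01,0.025
DRB1,*15:01,0.136
DRB1,OTHER,0.180
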