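"id","chain","cdr1_start","cdr1_end","cdr2_start","cdr2_end","cys_pos","j_start"
"VH1a1","heavy",26,35,49,65,89,100
"VH1a2","heavy",26,35,49,65,89,100
"VK1-1","kappa",23,34,49,56,90,100
"VK1-2","kappa",23,34,49,56,90,100
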