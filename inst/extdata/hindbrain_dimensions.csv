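time_hpf,L1_um,L2_um,p_um
11,300,283,240
12,310,162,248
13,320,120,256
14,330,104,265
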