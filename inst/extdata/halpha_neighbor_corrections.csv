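offset,neighbor_residue,atom,correction_ppm
1,P,HA,0.29
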