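cell_cycle	synthetic pathway fixture	E2F2	E2F3	Ccnd1	Cdk4	Cdk2	Cdkn1a	Rb1
melanogenesis	synthetic pathway fixture	Mitf	Tyr	Tyrp1	Dct
senescence	synthetic pathway fixture	Cdkn1a	Rb1	Trp53	Glb1
mtor_signaling	synthetic pathway fixture	Mtor	Akt1	Rps6kb1	Eif4ebp1
unrelated_metabolism	synthetic pathway fixture	Hk2	Pfkl	Aldoa	Gapdh	Pkm
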