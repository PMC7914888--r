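miRNA	gene
mmu-miR-129-3p	E2F2
mmu-miR-129-3p	Cdkn1a
mmu-miR-99b-5p	E2F2
mmu-miR-99b-5p	Mtor
mmu-miR-378-3p	E2F2
mmu-miR-378-3p	Ccnd1
mmu-miR-30d-5p	E2F2
mmu-miR-30d-5p	Ccnd1
mmu-miR-30d-5p	Cdk4
mmu-miR-129-5p	E2F2
mmu-miR-129-5p	Ccnd1
mmu-miR-129-5p	Cdk4
mmu-miR-21a-5p	E2F2
mmu-miR-335-3p	E2F2
mmu-miR-455-3p	Cdkn1a
mmu-miR-29c-3p	Cdkn1a
mmu-miR-29c-3p	Ccnd1
mmu-miR-335-5p	Cdkn1a
mmu-let-7e-5p	Ccnd1
mmu-let-7a-5p	Tyr
mmu-let-7a-5p	Ccnd1
mmu-let-7a-5p	Cdk4
mmu-let-7a-5p	E2F2
mmu-let-7a-5p	E2F3
mmu-let-7a-5p	Rb1
mmu-let-7b-5p	Tyr
mmu-let-7b-5p	Ccnd1
mmu-let-7b-5p	Cdk4
mmu-let-7b-5p	E2F2
mmu-let-7b-5p	E2F3
mmu-let-7b-5p	Rb1
mmu-miR-211-5p	Tyrp1
mmu-miR-211-5p	Dct
mmu-miR-148b-3p	Mitf
mmu-miR-27b-3p	Mitf
mmu-miR-27b-3p	Tyr
mmu-miR-27b-3p	Tyrp1
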