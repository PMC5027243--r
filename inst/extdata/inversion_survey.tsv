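group	n_with_inversion	n_screened	n_inversions
primary_breast	39	251	59
primary_osteosarcoma	4	35	7
brca_deficient_breast	19	33	46
radiation_associated	11	12	52
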