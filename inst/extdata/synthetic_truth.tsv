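protein_id	residue_i	residue_j
query	5	60
query	23	78
query	41	96
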