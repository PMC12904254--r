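# Reference two-chain Z-domain library scheme (synthetic example
# config shipped with the package; structure numbering)
chain_a_positions = 8,11,14,15,45
chain_b_positions = 29,30,33,43,44,47
degenerate_codon = DTS
alphabet = FILMV
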