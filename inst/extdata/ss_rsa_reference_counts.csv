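# Published large-scale tally of DSSP 8-state secondary structure against
# buried/exposed relative solvent accessibility (threshold RSA <= 0.15),
# from a non-redundant PDB-derived corpus of ~6.03 million residues.
# The printed_* rows/column carry the totals as published, so that
# recomputed margins can be checked against them.
rsa_bin,H,G,I,E,B,T,S,L,printed_sum
buried,1000536,82456,643,813132,29114,198608,180445,479341,2784275
exposed,999976,141550,391,466328,32103,446346,293307,865191,3245192
printed_sum,2000512,224006,1034,1279460,61217,644954,473752,1344532,6029467
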