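# Sequence constraints for the heterodimerization task (entity length 16,
# odd positions = chain A, even = chain B, designed residues 21 24 25 28 32
# 44 46 48 with wildtype F A L A G L V V).
# Homodimer identity penalty: 5 REU per identical designed pair beyond 6.
IDENTITY_PENALTY free=6 step=5 pairs=1:2,3:4,5:6,7:8,9:10,11:12,13:14,15:16
# Minimal-mutation penalty: 1 REU per mutation beyond 5 on either chain.
MUTATION_PENALTY free=5 step=1 positions=1,3,5,7,9,11,13,15 wildtype=FALAGLVV
MUTATION_PENALTY free=5 step=1 positions=2,4,6,8,10,12,14,16 wildtype=FALAGLVV
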