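# Binding-energy-gap fitness for the heterodimerization task.
# Species: A and B monomers, AB heterodimer (positive), AA and BB
# homodimers (negative).  States are bound programmatically (@) or may name
# structure/correspondence/secondary files.
STATE EA @
STATE EB @
STATE EAB @
STATE EAA @
STATE EBB @
SCALAR_EXPRESSION dGAB = EAB - EA - EB
SCALAR_EXPRESSION dGAAraw = EAA - 2*EA
SCALAR_EXPRESSION dGBBraw = EBB - 2*EB
# cap the negative-state binding energies at 0: no credit for unphysical
# clash-driven destabilization
SCALAR_EXPRESSION dGAA = min(dGAAraw, 0)
SCALAR_EXPRESSION dGBB = min(dGBBraw, 0)
SCALAR_EXPRESSION gaps = (dGAB - dGAA) + (dGAB - dGBB)
ENTITY_FUNCTION Eseq hetero_constraints.ent
# gap weight w = 2 (scanned 1..6 in production runs)
FITNESS EAB + 2*gaps + Eseq
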