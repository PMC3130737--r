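# Saturating fitness for the heterodimerization task: the heterodimer
# binding reward is capped at -24 REU, and the homodimers are driven toward
# a -12 REU binding-energy target by a bonus gated on the heterodimer
# binding well (-20 REU).
STATE EA @
STATE EB @
STATE EAB @
STATE EAA @
STATE EBB @
SCALAR_EXPRESSION dGAB = EAB - EA - EB
SCALAR_EXPRESSION dGAAraw = EAA - 2*EA
SCALAR_EXPRESSION dGBBraw = EBB - 2*EB
SCALAR_EXPRESSION b = ite(dGAB < -20, 1, 0)
SCALAR_EXPRESSION penAA = max(-12 - dGAAraw, 0)
SCALAR_EXPRESSION penBB = max(-12 - dGBBraw, 0)
SCALAR_EXPRESSION bindterm = max(dGAB, -24)
ENTITY_FUNCTION Eseq hetero_constraints.ent
# homodimer-destabilization bonus weight w2 = 1 (sampled 0.5..2 in runs)
FITNESS EAB + bindterm + 1*b*(penAA + penBB) + Eseq
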