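# One-against-many (orthogonal interface) fitness: species A keeps binding
# B, loses C and D.  Binding energies compare each dimer against monomer
# states sharing the same backbone conformation (EA_AB is the A monomer on
# the AB backbone, etc.); negative-state binding energies are capped at 0.
STATE EAB @
STATE EAC @
STATE EAD @
STATE EA_AB @
STATE EA_AC @
STATE EA_AD @
STATE EB @
STATE EC @
STATE ED @
SCALAR_EXPRESSION dGAB = EAB - EA_AB - EB
SCALAR_EXPRESSION dGAC = min(EAC - EA_AC - EC, 0)
SCALAR_EXPRESSION dGAD = min(EAD - EA_AD - ED, 0)
# gap weight w = 2 (scanned 1..12 in production runs)
FITNESS EAB + 2*((dGAB - dGAC) + (dGAB - dGAD))
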