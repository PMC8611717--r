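<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic four-site water descriptor for examples and tests.
     Epsilon magnitudes follow the experimental hydrogen-bond parameters of
     water (alpha ~ 2.8 for the two O-H donors, beta ~ 4.5 for the two lone
     pairs); positions are ideal tetrahedral directions on a sphere of the
     water van der Waals surface area (37.4 A^2). Not the published solvent
     library. -->
<ssipMolecule title="water (synthetic)">
  <atomArray>
    <atom elementType="O" x3="0.0" y3="0.0" z3="0.0"/>
    <atom elementType="H" x3="0.7569" y3="0.5859" z3="0.0"/>
    <atom elementType="H" x3="-0.7569" y3="0.5859" z3="0.0"/>
  </atomArray>
  <ssipArray surfaceArea="37.4">
    <ssip x3="0.9959" y3="0.9959" z3="0.9959" epsilon="2.8" area="9.35" meps="280"/>
    <ssip x3="0.9959" y3="-0.9959" z3="-0.9959" epsilon="2.8" area="9.35" meps="280"/>
    <ssip x3="-0.9959" y3="0.9959" z3="-0.9959" epsilon="-4.5" area="9.35" meps="-230"/>
    <ssip x3="-0.9959" y3="-0.9959" z3="0.9959" epsilon="-4.5" area="9.35" meps="-230"/>
  </ssipArray>
</ssipMolecule>
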