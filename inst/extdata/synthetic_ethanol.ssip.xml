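<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic seven-site ethanol descriptor for examples and tests.
     One O-H donor (alpha ~ 2.7), one oxygen acceptor (beta ~ 5.3) and five
     weakly polar alkyl-surface sites; positions schematic. Not the
     published solvent library. -->
<ssipMolecule title="ethanol (synthetic)">
  <atomArray>
    <atom elementType="C" x3="-1.25" y3="0.0" z3="0.0"/>
    <atom elementType="C" x3="0.25" y3="0.0" z3="0.0"/>
    <atom elementType="O" x3="0.85" y3="1.25" z3="0.0"/>
    <atom elementType="H" x3="1.81" y3="1.20" z3="0.0"/>
  </atomArray>
  <ssipArray surfaceArea="65.45">
    <ssip x3="2.6" y3="1.2" z3="0.0" epsilon="2.7" area="9.35" meps="270"/>
    <ssip x3="0.8" y3="2.6" z3="0.5" epsilon="-5.3" area="9.35" meps="-265"/>
    <ssip x3="-2.4" y3="0.0" z3="0.8" epsilon="0.6" area="9.35" meps="60"/>
    <ssip x3="-1.4" y3="-1.3" z3="-0.6" epsilon="0.4" area="9.35" meps="40"/>
    <ssip x3="0.4" y3="-1.3" z3="0.7" epsilon="-0.4" area="9.35" meps="-40"/>
    <ssip x3="-1.2" y3="1.3" z3="0.6" epsilon="0.2" area="9.35" meps="20"/>
    <ssip x3="0.9" y3="-0.4" z3="-1.2" epsilon="-0.2" area="9.35" meps="-20"/>
  </ssipArray>
</ssipMolecule>
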