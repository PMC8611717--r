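# synthetic solvent component index: name, SSIP XML file, molar volume (L/mol)
name	file	molar_volume
water	synthetic_water.ssip.xml	0.01807
ethanol	synthetic_ethanol.ssip.xml	0.05847
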