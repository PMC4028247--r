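tool	kind	target
YLoc	multi11	-
WoLFPSORT	multi11	-
TargetP	triple	-
Predotar	triple	-
MitoPred	single	mitochondrion
ChloroP	single	plastid
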