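patient	variant	variant_type	activity	inhibitor	manifestation
HA1	IVS 22 inversion	Inversion	10	NA	Elbow joint swelling
HA2	IVS 22 inversion	Inversion	6.6	NA	Intracranial hemorrhage
HA3	IVS 22 inversion	Inversion	2.6	Yes	Gum bleeding, ecchymoses
HA4	IVS 1 inversion	Inversion	8	NA	Ecchymoses after injuries, knee swelling
HA5	c.6496C>T (p.Arg2166*)	Nonsense	1.2	No	Eyelids swelling
HA6	c.5963_5964del (p.Glu1988Glyfs*3)	Small deletion	2	NA	?
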