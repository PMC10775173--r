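variant_class	sex	carries_variant
IVS22_inversion	male	TRUE
IVS22_inversion	male	TRUE
IVS22_inversion	male	TRUE
IVS22_inversion	male	TRUE
IVS22_inversion	male	TRUE
IVS22_inversion	male	TRUE
IVS22_inversion	male	TRUE
IVS22_inversion	male	FALSE
IVS22_inversion	male	FALSE
IVS22_inversion	male	FALSE
IVS22_inversion	male	FALSE
IVS22_inversion	male	FALSE
IVS22_inversion	female	TRUE
IVS22_inversion	female	FALSE
missense	male	TRUE
missense	male	TRUE
missense	male	TRUE
missense	male	FALSE
missense	male	FALSE
missense	male	FALSE
missense	male	FALSE
missense	female	TRUE
missense	female	FALSE
nonsense	male	TRUE
nonsense	male	TRUE
nonsense	male	TRUE
nonsense	male	TRUE
nonsense	male	FALSE
nonsense	male	FALSE
nonsense	male	FALSE
nonsense	female	FALSE
indel	male	TRUE
indel	male	TRUE
indel	male	TRUE
indel	male	FALSE
indel	male	FALSE
indel	male	FALSE
indel	male	FALSE
indel	female	FALSE
canonical_splice	male	FALSE
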