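# Consensus codon strings at the two kdr positions (V410L, F1534C) for
# field-collected Aedes aegypti populations from Pernambuco state.
# Codon key: V GTA; L TTA; F TTC; C TGC.
population	codon_410	codon_1534
Cedro	GTA	TGC
Recife	GTA	TGC
Santa Cruz do Capeberibe	GTA	TGC
Sao Jose do Egito	GTA	TGC
Afogados da Ingazeira	GTA	TTC
Serra Talhada	GTA	TTC
Itaiba	GTA	TGC
Arcoverde	GTA	TTC
Gloria do Goita	GTA	TTC
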