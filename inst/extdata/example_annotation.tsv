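category	gene
MAPK_signaling	MAP2K5
MAPK_signaling	MAP2K4
MAPK_signaling	MAPK14
vesicle_transport	CHMP3
energy_homeostasis	PRKAA1
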