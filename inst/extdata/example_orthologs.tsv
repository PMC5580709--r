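yeast_gene	human_gene	source
MKK1	MAP2K5	inparanoid
MKK1	MAP2K5	homologene
PBS2	MAP2K4	inparanoid
HOG1	MAPK14	inparanoid
VPS24	CHMP3	inparanoid
SNF1	PRKAA1	homologene
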