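species	state
Podospora_anserina	present
Neurospora_crassa	present
Grosmannia_clavigera	present
Botrytis_cinerea	present
Sclerotinia_sclerotiorum	present
Aspergillus_nidulans	present
Penicillium_chrysogenum	present
Ascosphaera_apis	absent
Mycosphaerella_graminicola	present
Cladosporium_fulvum	present
Tuber_melanosporum	present
Arthrobotrys_oligospora	absent
Saccharomyces_cerevisiae	absent
Candida_albicans	absent
Schizosaccharomyces_pombe	absent
Ustilago_maydis	absent
Cryptococcus_neoformans	absent
Rhizopus_oryzae	absent
Batrachochytrium_dendrobatidis	absent
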