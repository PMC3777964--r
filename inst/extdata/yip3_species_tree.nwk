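(((((((((Podospora_anserina,Neurospora_crassa),Grosmannia_clavigera),(Botrytis_cinerea,Sclerotinia_sclerotiorum)),(((Aspergillus_nidulans,Penicillium_chrysogenum),Ascosphaera_apis),(Mycosphaerella_graminicola,Cladosporium_fulvum))),Tuber_melanosporum),Arthrobotrys_oligospora),((Saccharomyces_cerevisiae,Candida_albicans),Schizosaccharomyces_pombe)),(Ustilago_maydis,Cryptococcus_neoformans)),(Rhizopus_oryzae,Batrachochytrium_dendrobatidis));
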