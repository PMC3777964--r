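Fixture notes
=============

yip3_species_tree.nwk / yip3_orf3_states.tsv
--------------------------------------------
Rooted species tree for the YIP3 3'-ORF presence/absence character, encoded
at class/order level following the standard fungal phylogeny:

  * Orbiliomycetes (Arthrobotrys oligospora) are the earliest-diverging
    Pezizomycotina class, then Pezizomycetes (Tuber melanosporum), then the
    split between (Leotiomycetes + Sordariomycetes) and
    (Eurotiomycetes + Dothideomycetes).
  * Outgroups: Saccharomycotina, Taphrinomycotina, Basidiomycota, and two
    early-diverging fungi.

Simplifications: only one or two representative species per class/order are
included; branch lengths are omitted (the character analysis is topological);
orders within Sordariomycetes (Sordariales vs Ophiostomatales) are collapsed
to a single trifurcation-free arrangement with Grosmannia clavigera sister to
(Podospora, Neurospora).  The 3' ORF is scored present in every
Pezizomycotina species except Ascosphaera apis and Arthrobotrys oligospora,
and absent in all non-Pezizomycotina fungi.

reporter_inserts.fasta
----------------------
The five dual-reporter insert sequences (also available from
reporter_inserts() in R); written by data-raw conventions from the package
constants so that file and code cannot drift apart (a checksum test guards
this).
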