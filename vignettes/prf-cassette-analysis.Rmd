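---
title: "Models and methods for -1 frameshift cassette analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for -1 frameshift cassette analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfscan)
```

This vignette is the package's account of the models it implements, the
parameters that matter, the numerical choices behind them, and what the
synthetic-data generators do and do not emulate.

## The cassette model

A −1 programmed ribosomal frameshift (PRF) cassette is modelled as five
ordered elements on one mRNA strand:

    [5' ORF] [slippery heptamer] [spacer] [stimulatory structure] [3' ORF, −1 frame]

All coordinates in the package are 0-based and half-open; 1-based codon
numbers appear only in human-facing reports. DNA is the internal alphabet;
RNA input is accepted and `U` is normalised to `T` on entry, and every
scanner and folder is invariant under the spelling.

## Slippery sites and tRNA re-pairing

A heptamer `X XXY YYZ` is registered with position 1 = `X`; the zero-frame
P-site codon occupies heptamer offsets 1–3 and the A-site codon offsets 4–6.
After a −1 slip the same tRNAs face the codons at offsets 0–2 and 3–5 (for
+1, offsets 2–4 and 5–7, using one base of context past the heptamer — the
two registers are treated symmetrically).

Re-pairing is evaluated by aligning the anticodon of the tRNA that decodes
the zero-frame codon antiparallel to the shifted codon and classifying each
position as Watson–Crick, wobble (G·U/U·G), inosine (I against U/C/A), or
mismatch. The packaged anticodon table follows budding-yeast wobble sparing
rules: the eight codon boxes read by inosine-34 anticodons (Ala, Arg `CGN`,
Ile, Leu `CUN`, Pro, Ser `UCN`, Thr, Val) use the single `I`-anticodon for
their U/C/A-ending codons — guaranteeing Ser `UCC` → `IGA`, the A-site tRNA
of the *PaYIP3* cassette — while the remaining two-codon U/C families share a
G34 anticodon (Phe `GAA`, Asn `GUU`, …), and A/G-ending codons take the
Watson–Crick complement. The G34 rule matters: without it the tRNA reading
`UUU` could not re-pair on `UUC`, and the single-P-site interpretation of the
`UUUCU`-type sites found in Capnodiales orthologs would be unreproducible.
The table simplifies isoacceptor detail (e.g. `AUA` is folded into the Ile
inosine family rather than its dedicated tRNA); it is a parameter
(`anticodon_table()`) and can be replaced wholesale.

**Acceptance rule.** A site is *tandem*-compatible when both tRNAs re-pair
without mismatch at codon positions 1 and 2; *single-P* when only the P-site
tRNA does. The third position — the one facing the anticodon wobble base 34
— is classified and reported but never disqualifies a site. This is the
classical tandem-slippage rule, and it is also forced by internal
consistency: every canonical `X XXY YYZ` heptamer re-pairs perfectly at
positions 1–2 but the reference IBV site itself (`U UUA AAC`) mismatches at
the wobble position of its A-site tRNA, so a strict three-position rule
would reject the very sites the consensus describes. The enumeration over
all 4^7 heptamers in the test suite verifies that the canonical set is a
subset of the relaxed acceptance set.

## Structure prediction

Full nearest-neighbour thermodynamics is deliberately out of scope. Instead
the stimulatory element is found by exhaustive enumeration under a
transparent scheme chosen so that the entire search space can be checked
against a brute-force oracle:

* a **stem** is 3–12 base pairs from {G·C, A·U, G·U} in up to three helices
  separated by at most two one-sided bulges of ≤5 nt;
* score = Σ pair scores (G·C = 3, A·U = 2, G·U = 1) − Σ (2 + 0.5·length) per
  bulge; loops are free;
* a **hairpin** is a single stem enclosing a loop of 3–30 nt;
* an **H-type pseudoknot** is an ordered pair of stems whose strands cross
  (`stem1.left < stem2.left < stem1.right < stem2.right`), scored as the sum
  of its stems, with loops L1, L2, L3 each ≤ 30 nt;
* the best structure wins; ties break deterministically (higher score →
  longer stem 1 → 5′-most stem 1 → 5′-most stem 2);
* structures scoring below `min_score = 12` (i.e. less than about four
  strong pairs after penalties) are reported as absent.

The search is exact (implemented in C++ for speed, replicated by a naive R
enumeration in the tests), so reported scores are recomputable from the
declared function — `score_structure()` does exactly that.

**The spacer floor.** Cassette-level folding (`fold_downstream()`,
`scan_cassette()`) starts the search window `min_spacer = 2` nt after the
heptamer, keeping the first bases unpaired. Mechanistically the mRNA
immediately 3′ of the A-site codon is inside the ribosome's mRNA channel
when the structure must resist unwinding, and 2 nt is the smallest spacer
observed in a functional −1 cassette (this gene family; typical viral
spacers are 5–9 nt). The floor has a visible consequence on the *PaYIP3*
cassette: the unconstrained argmax would extend stem 1 by one extra outer
G·C pair into the spacer, and with the floor the optimum is exactly the
structure supported by comparative data — a 10-pair stem 1
(`GGAGGUGGUC` paired to `GACCAC`+`CUCC`) interrupted by the 3-nt `GAG`
bulge, crossed by a 5-pair stem 2 reaching the 3′ `CGCCCC`, giving a 2-nt
spacer. A grid exploration over pair scores, bulge penalties and loop
minima showed the (spacer 2, bulge 3) outcome is stable across all
wobble-permitting parameterisations once the floor is in place; the scoring
defaults above were kept unchanged.

`cassette_features()` derives the three comparative hallmarks: spacer
length, total stem-1 bulge, and the run of contiguous G·C pairs at the base
of stem 1 (the IBV-like G-C stretch; 2 on this cassette).

## ORF pairs and the fusion product

`find_orf_pairs()` pairs every ATG-initiated, stop-terminated 5′ ORF with
every downstream stop-to-stop ORF in a different frame that begins before
the 5′ ORF's stop codon ends (a `max_gap` tolerance covers annotation slop)
and extends past it. The required shift is the frame residue: 1 → +1,
2 → −1.

For a tandem slip at a heptamer starting at `p`, the fusion protein is the
zero-frame translation through the A-site codon (half-open end `p+7`)
concatenated with the shifted-register translation from `p+7+shift` to the
3′ ORF's stop; the slippage-codon residue is taken from the zero-frame codon
because the same aminoacyl-tRNA re-pairs. Under single-P slippage the
zero-frame part ends with the P codon (`p+4`) and reading resumes at
`p+4+shift`. Any stop encountered before the 3′ ORF's own stop signals an
invalid site/pair combination and is an error, not a silent truncation.
Masses use average (not monoisotopic) residue weights by default, matching
gel-derived kDa figures; the 5′-ORF product of the natural gene runs at
19.5 kDa and the fusion at 61.6 kDa, and `yip3_cds_report()` reproduces
those numbers from the full CDS when the user supplies it (the genome
annotation is not redistributable with the package).

## Conservation analysis

`align_cassettes()` is a convenience global aligner (optimal pairwise
Needleman–Wunsch with affine gaps via Biostrings; deterministic
star-progressive merging for more than two sequences); pre-computed
alignments pass through unchanged, and serious comparative work should use a
structure-aware aligner upstream.

Per column pair of a reference structure, `column_pair_stats()` counts the
distinct compatible pair types among {C-G, G-C, A-U, U-A, G-U, U-G} (the
covariation signal), incompatible rows (structure disruption) and gapped
rows. `find_compensatory()` classifies each species' pair against the
reference row: both bases changed with pairing preserved → *compensatory*;
pairing preserved through a single-base change → *wobble_shift* (any such
change necessarily passes through a G·U pair); pairing lost → *disruptive*.
Species are compared to the reference structure only — no per-species
refolding — matching how compensatory support is usually presented.

`fitch_map()` performs minimum-change (Fitch/Hartigan) reconstruction of the
binary 3′-ORF character on a rooted tree, multifurcations included. Ties at
the root resolve to the outgroup state (`absent` by default), and a child
keeps its parent's state whenever its candidate set allows, making the
event list deterministic. Every change is labelled a gain or a loss on its
edge. The packaged tree transcribes the comparative analysis at class/order
level (Orbiliomycetes earliest-diverging; see `inst/extdata/README` for the
simplifications); on it the reconstruction needs exactly one gain (after the
Orbiliomycetes split) and one loss (*A. apis*), which the tests confirm
against exhaustive enumeration of all ancestral assignments.

## Reporter quantification

Efficiency is the ratio of construct-level ratio means,
`100 · mean(luc/βgal | test) / mean(luc/βgal | control)` — a ratio of means
rather than a mean of replicate-wise ratios because test and control
replicates are unpaired crude extracts. The standard error propagates the
two ratio-mean standard errors to first order. β-galactosidase activities
must be strictly positive; nothing else is normalised or
background-subtracted.

`mann_whitney_exact()` computes U with mid-rank ties and the exact two-sided
p by enumerating all `choose(n_x+n_y, n_x)` labelings (counting those with
|U − n_x·n_y/2| at least as large as observed); beyond 20 observations it
falls back, flagged, to the tie-corrected normal approximation. Validity
under the null is checked deterministically in the tests: over the full
enumeration at the assay's 6+6 design, P(p ≤ α) ≤ α at every α. Pairwise
construct comparisons report unadjusted p-values with a Holm-adjusted column
alongside.

## Synthetic data: what it does and does not emulate

`make_cassette()` realises a `cassette_spec()` exactly: default geometry
mirrors the natural cassette (heptamer `TTTTTCC`, spacer 2 nt, 10-pair
stem 1 with a 3-nt bulge, 5-pair stem 2, loops 2/2/7 nt), at desk scale
(30-codon 5′ ORF, 25 shifted-register codons — the natural gene is longer).
Filler is GC-balanced uniform i.i.d.; stems are planted by construction,
with the bases flanking each stem end fixed to `A` so planted helices cannot
silently extend, and an all-`A` bulge guarded against sliding. Shifted-
register stop codons between the slip and the planted stop are repaired in
free positions (any codon containing `C` is a non-stop). Every emitted
cassette is re-validated — planted site detectable, planted structure the
unique argmax of the search, exactly one ORF pair — and colliding fillers
are resampled within the seeded stream, so generation is bit-reproducible
given the seed.

`make_family()` evolves the base cassette down a tree by per-edge
substitutions: stem pairs mutate as compensatory double substitutions
(pairing preserved) or disruptive single-base changes in a controlled
proportion; the heptamer, start codon and both stops are protected, and
mutations that would truncate either ORF are redrawn, so cassette presence
stays detectable. Subtrees below designated loss nodes are truncated at the
5′ ORF's stop and stop evolving. `make_reporter()` draws replicate
luciferase/β-gal ratios log-normally (mean held exactly at the nominal
value; CV default 0.1, reflecting multiplicative activity-assay noise)
around the control ratio and around control × efficiency/100;
`reporter_calibration()` pins the two quantified constructs at 1 % and
0.3 %.

What the generators do **not** emulate: codon-usage bias, indels and
alignment uncertainty, rate heterogeneity and multiple hits along branches,
structure heterogeneity across the family (every member keeps the reference
geometry), correlated assay noise and plate effects. Passing the round-trip
tests therefore demonstrates internal correctness of detection, folding,
feature extraction and estimation — not performance on diverged genomic
sequence, where alignment quality and structure variation dominate.

## Numerical choices and degenerate inputs

* Exhaustive searches bound the window at 120 nt (the cassette-level window
  is 80 nt past the spacer floor); longer windows are refused with advice
  rather than silently truncated.
* Scores are compared with an absolute tolerance of 1e-9 when tie-breaking.
* Empty sequences are legal only in FASTA I/O round-trips; scanners return
  empty tibbles on windows shorter than a heptamer; `predict_*` return
  `NULL` below the score threshold, and downstream feature code treats that
  as "no structure" rather than an error.
* The exact Mann–Whitney enumeration is capped at 20 observations
  (`choose(20,10)` = 184k labelings); the flag in `method` makes the
  fallback visible in reports.
* Problem sizes in the test suite (window lengths ≤ 40 nt for oracle
  equivalence, 100 seeded cassettes for round trips, 1000 seeded trials for
  estimator calibration) were chosen as the smallest sizes that exercise
  every code path with comfortable statistical margins.

## Known limitations

The structure model ranks by pair counts, not free energy, so its scores are
not comparable to thermodynamic predictions and the hairpin/pseudoknot call
near the threshold (the *T. melanosporum* situation, where a stem-loop
rather than a pseudoknot may form) is sensitive to `min_score`; the package
therefore reports both best structures with their scores and leaves the
call to the threshold. Only H-type (two crossing stems) pseudoknots are
considered — no kissing loops or triple helices — and trans-acting factors
that may stimulate frameshifting in the native host are outside the model.
The built-in aligner is a convenience, not a replacement for
structure-aware alignment. The anticodon table is a yeast-style
simplification; organisms with unusual decoding rules need a custom table.
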