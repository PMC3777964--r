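# Packaged reference sequences: the dual-reporter insert sequences used to
# quantify frameshifting on the PaYIP3 cassette in S. cerevisiae, and the two
# reference slippery motifs.

#' Dual-reporter insert sequences for the PaYIP3 frameshift cassette
#'
#' The five insert sequences cloned between the beta-galactosidase and firefly
#' luciferase reporters to measure -1 frameshifting on the *Podospora
#' anserina* *PaYIP3* cassette:
#'
#' * `Podo-1` - the natural -1 frameshift window (slippery `TTTTTCC` plus
#'   downstream pseudoknot); the luciferase reporter requires a -1 shift.
#' * `Podo0` - in-frame control, `Podo-1` with one extra `G` at the 5' end.
#' * `IBV-Podo-1 sp6` - IBV (Infectious Bronchitis Virus) slippery site
#'   `TTTAAAC` with the 6-nt IBV spacer ahead of the *PaYIP3* pseudoknot.
#' * `IBV-Podo-1 sp2` - IBV slippery site with the 2-nt *PaYIP3* spacer.
#' * `IBV-Podo0` - IBV slippery site placed out of frame (background control).
#'
#' @return Tibble with columns `id`, `seq`, `is_rna`.
#' @examples
#' reporter_inserts()
#' @export
reporter_inserts <- function() {
  tibble(
    id = c("Podo-1", "Podo0", "IBV-Podo-1_sp6", "IBV-Podo-1_sp2",
           "IBV-Podo0"),
    seq = c(
      "GCTTTTTCCGGGGAGGTGGTCTAGGTGGTCGGCCACGAGCTCCCAAATTTTCGCCCCAT",
      "GGCTTTTTCCGGGGAGGTGGTCTAGGTGGTCGGCCACGAGCTCCCAAATTTTCGCCCCAT",
      "TATTTAAACGGGTACGGGAGGTGGTCAAGGTGGTCGGCCACGAGCTCCCAAATTTTCGCCCC",
      "TATTTAAACCGGGGAGGTGGTCTAGGTGGTCGGCCACGAGCTCCCAAATTTTCGCCCCA",
      "TTATTTAAACGGGTACGGGAGGTGGTCAAGGTGGTCGGCCACGAGCTCCCAAATTTTCGCCCCAT"
    ),
    is_rna = FALSE
  )
}

#' Reference slippery heptamers
#'
#' The *PaYIP3* heptamer (`U UUU UCC`, shown as DNA) and the canonical IBV
#' heptamer (`T TTA AAC`).
#'
#' @return Named character vector of heptamers (DNA alphabet).
#' @export
slippery_motifs <- function() {
  c(PaYIP3 = "TTTTTCC", IBV = "TTTAAAC")
}

#' Packaged species tree and 3'-ORF states for the YIP3 family
#'
#' Loads the packaged fungal species tree (Newick) and the binary
#' presence/absence states of the frameshift-accessible 3' ORF, transcribed at
#' class/order level from the comparative analysis of the YIP3 frameshift
#' cassette (see `inst/extdata/README` for the simplifications made).
#'
#' @return List with elements `tree` (an [ape::phylo]) and `states` (tibble
#'   with columns `species`, `state`).
#' @export
yip3_character_data <- function() {
  nwk <- system.file("extdata", "yip3_species_tree.nwk", package = "prfscan")
  tsv <- system.file("extdata", "yip3_orf3_states.tsv", package = "prfscan")
  tree <- ape::read.tree(nwk)
  states <- utils::read.delim(tsv, stringsAsFactors = FALSE) %>% as_tibble()
  list(tree = tree, states = states)
}

#' Frameshift report for a full YIP3-family CDS
#'
#' Given the full genomic CDS of a YIP3-family gene carrying the frameshift
#' (for *P. anserina*, CDS Pa_1_8470 from the genome annotation), locates the
#' slippery site, reports its codon number (1-based, as used in gene
#' annotation), and computes the masses of the 5'-ORF product and of the
#' frameshift fusion product.
#'
#' @param cds_fasta Path to a FASTA file holding the CDS (first record used).
#' @param shift Frameshift direction (default -1).
#' @return One-row tibble: `heptamer`, `site_start` (0-based), `site_codon`
#'   (1-based codon number of the heptamer's P codon), `orf5_kda`,
#'   `fusion_kda`.
#' @export
yip3_cds_report <- function(cds_fasta, shift = -1L) {
  seqs <- read_fasta(cds_fasta)
  if (nrow(seqs) == 0) abort("CDS FASTA is empty")
  seq <- seqs$seq[1]
  pairs <- find_orf_pairs(seq, min_aa5 = 50L, min_aa3 = 50L)
  pairs <- pairs[pairs$shift == shift, ]
  if (nrow(pairs) == 0) abort("No overlapping ORF pair with that shift")
  pair <- pairs[1, ]
  sites <- scan_slippery(seq, mode = "relaxed", shift = shift)
  sites <- sites[sites$start + 7L > pair$overlap_start &
                   sites$start + 7L <= pair$overlap_end &
                   (sites$start + 1L - pair$orf5_start) %% 3L == 0L, ]
  if (nrow(sites) == 0) abort("No slippery site inside the ORF overlap")
  site <- sites[1, ]
  fus <- build_fusion(seq, pair, site)
  orf5_aa <- translate_cds(seq, start = pair$orf5_start)
  tibble(
    heptamer = site$heptamer,
    site_start = site$start,
    site_codon = (site$start + 1L - pair$orf5_start) %/% 3L + 1L,
    orf5_kda = protein_mass(orf5_aa) / 1000,
    fusion_kda = fus$mass_da / 1000
  )
}
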