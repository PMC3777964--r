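# Slippery-site scanning and tRNA re-pairing classification.
#
# A -1 PRF slippery heptamer X XXY YYZ is registered with position 1 = X
# (0-based offset 0 within the heptamer).  The zero-frame P-site codon
# occupies heptamer offsets 1-3 and the A-site codon offsets 4-6; after a -1
# shift the same tRNAs face the codons at offsets 0-2 and 3-5 (for +1,
# offsets 2-4 and 5-7, which uses one base of context past the heptamer).

#' Anticodon lookup table
#'
#' Maps each sense codon (DNA alphabet) to the anticodon (5'->3', RNA alphabet
#' plus `I` for inosine) of the tRNA that decodes it, following budding-yeast
#' wobble sparing rules:
#'
#' * the eight codon boxes read by inosine-34 anticodons (Ala, Arg `CGN`,
#'   Ile, Leu `CUN`, Pro, Ser `UCN`, Thr, Val): codons ending in `T`, `C` or
#'   `A` are decoded by the single `I`-starting anticodon of the family
#'   (e.g. Ser `TCC` by `IGA`);
#' * in the remaining families, codons ending in `T` or `C` share a G34
#'   anticodon (e.g. Phe `TTT`/`TTC` by `GAA`), so the U-ending codon is read
#'   through a G.U wobble;
#' * codons ending in `A` or `G` get the Watson-Crick reverse complement.
#'
#' @return Tibble with columns `codon` (DNA) and `anticodon` (RNA/I, 5'->3').
#' @export
anticodon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  rc_rna <- function(codon) {
    chartr("ACGT", "UGCA", paste(rev(strsplit(codon, "")[[1]]), collapse = ""))
  }
  anticodon <- vapply(codons, rc_rna, character(1))
  # codon boxes read by inosine-34 anticodons (first two codon bases)
  inosine_boxes <- c("GC", "CG", "AT", "CT", "CC", "TC", "AC", "GT")
  for (i in seq_along(codons)) {
    prefix <- substr(codons[i], 1, 2)
    third <- substr(codons[i], 3, 3)
    stem <- chartr("ACGT", "UGCA",
                   paste(rev(strsplit(prefix, "")[[1]]), collapse = ""))
    if (prefix %in% inosine_boxes && third %in% c("T", "C", "A")) {
      anticodon[i] <- paste0("I", stem)
    } else if (third %in% c("T", "C")) {
      # G34 anticodon shared by the T/C-ending codon pair
      anticodon[i] <- paste0("G", stem)
    }
  }
  tibble(codon = codons, anticodon = unname(anticodon))
}

.pair_class <- function(codon_base, anticodon_base) {
  # codon base in DNA alphabet, anticodon base in RNA/I alphabet
  wc <- c(A = "U", C = "G", G = "C", T = "A")
  if (anticodon_base == "I") {
    if (codon_base %in% c("T", "C", "A")) return("inosine")
    return("mismatch")
  }
  if (wc[[codon_base]] == anticodon_base) return("WC")
  if ((codon_base == "G" && anticodon_base == "U") ||
      (codon_base == "T" && anticodon_base == "G")) {
    return("wobble")
  }
  "mismatch"
}

#' Classify codon/anticodon re-pairing after a frameshift
#'
#' Aligns the anticodon of the tRNA decoding `codon_from` (the zero-frame
#' codon) antiparallel to `codon_to` (the shifted-frame codon) and classifies
#' each of the three positions, reported codon-5'->3', as `WC` (Watson-Crick),
#' `wobble` (G.U/U.G), `inosine` (I against U, C or A) or `mismatch`.
#'
#' @param codon_from,codon_to Codons (DNA or RNA spelling).
#' @param table Anticodon table, as from [anticodon_table()].
#' @return Character vector of three pair classes.
#' @examples
#' repair_pairs("TCC", "TTC")   # Ser (IGA) on the -1 codon: WC, wobble, inosine
#' @export
repair_pairs <- function(codon_from, codon_to, table = anticodon_table()) {
  codon_from <- .check_dna(codon_from)
  codon_to <- .check_dna(codon_to)
  stopifnot(nchar(codon_from) == 3, nchar(codon_to) == 3)
  hit <- table$anticodon[table$codon == codon_from]
  if (length(hit) != 1) {
    abort(paste0("Codon ", codon_from,
                 " is not a sense codon in the anticodon table"))
  }
  if (.codon_is_stop(codon_to)) {
    abort(paste0("Codon ", codon_to, " is a stop codon"))
  }
  ac <- strsplit(hit, "")[[1]]          # 5'->3': positions 34, 35, 36
  ct <- strsplit(codon_to, "")[[1]]     # 5'->3': positions 1, 2, 3
  # antiparallel: codon position 1 pairs anticodon position 3 (= ac[3])
  vapply(1:3, function(i) .pair_class(ct[i], ac[4 - i]), character(1))
}

.site_codons <- function(seq, start, shift) {
  # zero-frame and shifted-frame P/A codons for a heptamer at `start`
  sub <- function(a, b) substr(seq, a + 1L, b)  # 0-based half-open
  p0 <- sub(start + 1L, start + 4L)
  a0 <- sub(start + 4L, start + 7L)
  if (shift == -1L) {
    ps <- sub(start, start + 3L)
    as <- sub(start + 3L, start + 6L)
  } else {
    ps <- sub(start + 2L, start + 5L)
    as <- sub(start + 5L, start + 8L)
  }
  list(p0 = p0, a0 = a0, p_shift = ps, a_shift = as)
}

.repair_ok <- function(classes) {
  # Re-pairing is judged at codon positions 1 and 2 only: after slippage the
  # tRNA must re-pair correctly at the first two positions, while the third
  # (facing the anticodon wobble base 34) tolerates mismatches, as in the
  # canonical X XXY YYZ sites where the shifted wobble pairing is routinely
  # non-cognate.  The position-3 class is still computed and reported.
  all(classes[1:2] != "mismatch")
}

.build_site <- function(seq, start, shift, table) {
  cod <- .site_codons(seq, start, shift)
  hept <- substr(seq, start + 1L, start + 7L)
  p_cls <- tryCatch(repair_pairs(cod$p0, cod$p_shift, table),
                    error = function(e) rep("mismatch", 3))
  a_cls <- tryCatch(repair_pairs(cod$a0, cod$a_shift, table),
                    error = function(e) rep("mismatch", 3))
  p_ok <- .repair_ok(p_cls)
  a_ok <- .repair_ok(a_cls)
  model <- if (p_ok && a_ok) "tandem" else if (p_ok) "single_P" else
    "incompatible"
  tibble(
    start = start, heptamer = hept, shift = shift,
    canonical = .is_canonical(hept),
    p_codon0 = cod$p0, a_codon0 = cod$a0,
    p_codon_shift = cod$p_shift, a_codon_shift = cod$a_shift,
    p_classes = list(p_cls), a_classes = list(a_cls),
    model = model
  )
}

.is_canonical <- function(hept) {
  h <- strsplit(hept, "")[[1]]
  h[1] == h[2] && h[2] == h[3] && h[4] == h[5] && h[5] == h[6]
}

#' Construct a slippery site at a known position
#'
#' Builds the full site record (codons in both registers, per-tRNA re-pairing
#' classes, slippage model) for the heptamer starting at 0-based `start`.
#'
#' @param seq DNA/RNA string.
#' @param start 0-based offset of the heptamer's first base (the `X` of
#'   `X XXY YYZ`).
#' @param shift `-1` or `+1`.
#' @param table Anticodon table.
#' @return One-row tibble (see [scan_slippery()] for columns).
#' @export
slippery_site <- function(seq, start, shift = -1L, table = anticodon_table()) {
  seq <- .check_dna(seq)
  n <- nchar(seq)
  need <- if (shift == 1L) start + 8L else start + 7L
  if (start < 0L || need > n) {
    abort("Heptamer (plus shifted-register context) outside sequence")
  }
  .build_site(seq, as.integer(start), as.integer(shift), table)
}

#' Scan a sequence for slippery heptamers
#'
#' In `canonical` mode only heptamers matching `X XXY YYZ` (first three bases
#' identical, next three identical) are returned.  In `relaxed` mode a
#' heptamer qualifies when both the P- and the A-site tRNA re-pair with their
#' shifted-frame codons without a mismatch at codon positions 1 and 2
#' (Watson-Crick, wobble and inosine pairs all count; the third position,
#' which faces the anticodon wobble base, is classified and reported but does
#' not disqualify a site -- canonical sites routinely re-pair non-cognately
#' there).  Every canonical heptamer is therefore also accepted in relaxed
#' mode, as are non-consensus sites such as the *PaYIP3* `T TTT TCC`, whose
#' A-site tRNA (Ser `IGA`) in fact re-pairs at all three positions.
#' Results are invariant under DNA/RNA spelling of the input.
#'
#' @param seqs A data frame of sequences (columns `id`, `seq`) or a single
#'   DNA/RNA string.
#' @param mode `"relaxed"` (default) or `"canonical"`.
#' @param shift `-1` (default) or `+1`.
#' @param table Anticodon table.
#' @return Tibble of sites sorted by `id` then `start` (0-based), with the
#'   heptamer, codons in both registers, per-position pair classes
#'   (`p_classes`, `a_classes`, list-columns) and the slippage `model`
#'   (`tandem`, `single_P` or `incompatible`).
#' @examples
#' scan_slippery("GCTTTTTCCGGG")          # the PaYIP3 site at start 2
#' @export
scan_slippery <- function(seqs, mode = c("relaxed", "canonical"),
                          shift = -1L, table = anticodon_table()) {
  mode <- match.arg(mode)
  shift <- as.integer(shift)
  stopifnot(shift %in% c(-1L, 1L))
  if (is.character(seqs)) {
    seqs <- tibble(id = "seq", seq = seqs)
  }
  # memoized mismatch-free re-pairing over (codon_from, codon_to)
  memo <- new.env(parent = emptyenv())
  ok_repair <- function(from, to) {
    key <- paste0(from, to)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (.codon_is_stop(from) || .codon_is_stop(to)) FALSE
    else .repair_ok(repair_pairs(from, to, table))
    memo[[key]] <- val
    val
  }
  res <- purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    id <- seqs$id[i]
    seq <- .check_dna(seqs$seq[i])
    n <- nchar(seq)
    hi <- if (shift == 1L) n - 8L else n - 7L
    if (n < 7 || hi < 0L) return(tibble())
    p <- 0:hi
    hept <- substring(seq, p + 1L, p + 7L)
    keep <- if (mode == "canonical") {
      vapply(hept, .is_canonical, logical(1))
    } else {
      p0 <- substring(seq, p + 2L, p + 4L)
      a0 <- substring(seq, p + 5L, p + 7L)
      if (shift == -1L) {
        ps <- substring(seq, p + 1L, p + 3L)
        as <- substring(seq, p + 4L, p + 6L)
      } else {
        ps <- substring(seq, p + 3L, p + 5L)
        as <- substring(seq, p + 6L, p + 8L)
      }
      vapply(seq_along(p), function(k) {
        ok_repair(p0[k], ps[k]) && ok_repair(a0[k], as[k])
      }, logical(1))
    }
    hits <- p[keep]
    if (length(hits) == 0) return(tibble())
    sites <- purrr::map_dfr(hits, function(pp) .build_site(seq, pp, shift,
                                                           table))
    mutate(sites, id = id, .before = 1)
  })
  if (nrow(res) == 0) {
    return(tibble(id = character(), start = integer(), heptamer = character(),
                  shift = integer(), canonical = logical(),
                  p_codon0 = character(), a_codon0 = character(),
                  p_codon_shift = character(), a_codon_shift = character(),
                  p_classes = list(), a_classes = list(), model = character()))
  }
  arrange(res, .data$id, .data$start)
}

#' Classify the slippage model of a site
#'
#' `tandem` when both tRNAs re-pair in the shifted frame without a mismatch
#' at codon positions 1-2, `single_P` when only the P-site tRNA does,
#' `incompatible` otherwise.
#'
#' @param site A one-row site tibble from [slippery_site()] or
#'   [scan_slippery()].
#' @return `"tandem"`, `"single_P"` or `"incompatible"`.
#' @export
classify_site <- function(site) {
  stopifnot(is.data.frame(site), nrow(site) == 1,
            all(c("p_classes", "a_classes") %in% names(site)))
  p_ok <- .repair_ok(site$p_classes[[1]])
  a_ok <- .repair_ok(site$a_classes[[1]])
  if (p_ok && a_ok) "tandem" else if (p_ok) "single_P" else "incompatible"
}
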