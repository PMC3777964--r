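# Overlapping-ORF detection and frameshift fusion-product construction.
#
# A -1 PRF gene model is a short 5' ORF and a longer 3' ORF in a different
# frame, joined during translation by slippage at a heptamer inside their
# overlap.  Frames are relative to the window start; the required shift is
# ((orf3.frame - orf5.frame) mod 3), with residue 1 read as +1 and residue 2
# as -1 (a -1 slip and a +2 slip are indistinguishable at the codon level).

#' Find overlapping ORF pairs joinable by a frameshift
#'
#' Pairs every qualifying 5' ORF (ATG-initiated by default, with a terminal
#' stop) with every downstream stop-to-stop ORF in a different frame that
#' starts before the 5' ORF's stop codon ends (or within `max_gap` nt of it)
#' and extends past it.
#'
#' @param seq DNA/RNA string.
#' @param min_aa5,min_aa3 Minimum protein lengths of the 5' and 3' ORFs.
#' @param max_gap Maximum allowed gap (nt) between the 5' ORF end and the 3'
#'   ORF start (default 0: the ORFs must overlap).
#' @param require_atg5 Require the 5' ORF to start at ATG.
#' @return Tibble sorted by `orf5_start` then `orf3_start` with 0-based
#'   half-open coordinates, frames, protein sequences, the required `shift`
#'   (-1 or +1) and the `overlap_start`/`overlap_end` window where a shift
#'   can join the two ORFs.
#' @export
find_orf_pairs <- function(seq, min_aa5 = 10L, min_aa3 = 10L, max_gap = 0L,
                           require_atg5 = TRUE) {
  stopifnot(min_aa5 >= 1, min_aa3 >= 1, max_gap >= 0)
  seq <- .check_dna(seq)
  orf5s <- find_orfs(seq, min_aa = min_aa5, require_atg = require_atg5) %>%
    filter(.data$has_terminal_stop)
  orf3s <- find_orfs(seq, min_aa = min_aa3, require_atg = FALSE)
  empty <- tibble(
    orf5_start = integer(), orf5_end = integer(), orf5_frame = integer(),
    orf5_aa = character(), orf3_start = integer(), orf3_end = integer(),
    orf3_frame = integer(), orf3_aa = character(), shift = integer(),
    overlap_start = integer(), overlap_end = integer()
  )
  if (nrow(orf5s) == 0 || nrow(orf3s) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(orf5s))) {
    for (j in seq_len(nrow(orf3s))) {
      o5 <- orf5s[i, ]
      o3 <- orf3s[j, ]
      if (o3$frame == o5$frame) next
      if (o3$start <= o5$start) next
      if (o3$end <= o5$end) next
      if (o3$start > o5$end + max_gap) next
      res <- (o3$frame - o5$frame) %% 3L
      shift <- if (res == 1L) 1L else -1L
      out[[length(out) + 1L]] <- tibble(
        orf5_start = o5$start, orf5_end = o5$end, orf5_frame = o5$frame,
        orf5_aa = o5$aa_seq, orf3_start = o3$start, orf3_end = o3$end,
        orf3_frame = o3$frame, orf3_aa = o3$aa_seq, shift = shift,
        overlap_start = o3$start, overlap_end = o5$end
      )
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) %>% arrange(.data$orf5_start, .data$orf3_start)
}

#' Reading-frame shift required by a reporter insert of a given length
#'
#' In a dual-reporter construct with in-frame flanks, the shift the ribosome
#' must make inside the insert for the downstream reporter to be translated
#' in frame is determined by the insert length modulo 3: multiples of three
#' need no shift, a residue of 2 needs a -1 shift, a residue of 1 a +1 shift.
#'
#' @param insert_len Insert length(s) in nucleotides.
#' @return Integer vector of required shifts in \{-1, 0, +1\}.
#' @examples
#' classify_insert_frame(c(59, 60, 1))   # -1, 0, +1
#' @export
classify_insert_frame <- function(insert_len) {
  stopifnot(all(insert_len >= 0))
  c(0L, 1L, -1L)[(as.integer(insert_len) %% 3L) + 1L]
}

#' Construct the predicted frameshift fusion protein
#'
#' Under tandem slippage at a heptamer starting at `p`, translation proceeds
#' in the zero frame through the A-site codon (ending at `p+6`, half-open
#' `p+7`) and resumes at `p+7+shift` in the shifted register; under single
#' P-site slippage it proceeds through the P-site codon (half-open `p+4`) and
#' resumes at `p+4+shift`.  Translation then continues to the 3' ORF's stop.
#' The amino acid at the slippage codon is therefore taken from the zero-frame
#' codon (the same tRNA re-pairs and carries the same residue).
#'
#' @param seq DNA/RNA string.
#' @param orf_pair One row of [find_orf_pairs()].
#' @param site One-row slippery-site tibble; must lie inside the pair's
#'   overlap window, on the 5' ORF's codon grid, with a matching shift.
#' @return One-row tibble: `aa_seq`, `mass_da`, `part5_aa`, `part3_aa`
#'   (residues encoded before/after the shift), `site_start`, `model`,
#'   `shift`.
#' @export
build_fusion <- function(seq, orf_pair, site) {
  seq <- .check_dna(seq)
  stopifnot(nrow(orf_pair) == 1, nrow(site) == 1)
  if (site$shift != orf_pair$shift) {
    abort("Site shift does not match the ORF pair's required shift")
  }
  p <- site$start
  if (p + 7L > orf_pair$overlap_end || p + 7L <= orf_pair$overlap_start) {
    abort("Slippery site lies outside the ORF pair's overlap window")
  }
  if ((p + 1L - orf_pair$orf5_start) %% 3L != 0L) {
    abort("Heptamer is not on the 5' ORF's codon grid (P codon misaligned)")
  }
  model <- if ("model" %in% names(site)) site$model else "tandem"
  if (model == "incompatible") {
    abort("Site is incompatible with slippage under both models")
  }
  cut0 <- if (model == "tandem") p + 7L else p + 4L
  resume <- cut0 + site$shift
  part5 <- translate_cds(substr(seq, orf_pair$orf5_start + 1L, cut0),
                         stop_policy = "read_through")
  if (grepl("*", part5, fixed = TRUE)) {
    stop_codon <- regexpr("*", part5, fixed = TRUE)[1] - 1L
    abort(paste0("Internal stop in the zero-frame segment at codon index ",
                 stop_codon, " (0-based from the 5' ORF start)"))
  }
  part3_full <- translate_cds(seq, start = resume,
                              stop_policy = "read_through")
  stop_rel <- regexpr("*", part3_full, fixed = TRUE)[1]
  expected_stop <- (orf_pair$orf3_end - 3L - resume) %/% 3L
  if (stop_rel == -1 || (stop_rel - 1L) != expected_stop) {
    where <- if (stop_rel == -1) "none found" else
      paste0("codon at offset ", resume + 3L * (stop_rel - 1L))
    abort(paste0(
      "Shifted-register translation does not terminate at the 3' ORF stop (",
      where, "): invalid site/pair combination"))
  }
  part3 <- substr(part3_full, 1L, stop_rel - 1L)
  aa <- paste0(part5, part3)
  tibble(
    aa_seq = aa, mass_da = protein_mass(aa),
    part5_aa = nchar(part5), part3_aa = nchar(part3),
    site_start = p, model = model, shift = site$shift
  )
}
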