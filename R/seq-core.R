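#' @useDynLib prfscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter arrange select bind_rows bind_cols
#'   group_by ungroup summarise left_join n row_number across pull rename
#' @importFrom rlang .data abort
NULL

# All coordinates in this package are 0-based, half-open: a feature covering
# the first three bases of a sequence has start 0 and end 3.  Conversion to
# the 1-based coordinates used in written reports happens only at the
# reporting layer.

VALID_BASES <- c("A", "C", "G", "T")

#' Read nucleotide sequences from a FASTA file
#'
#' Reads a (possibly multi-record, wrapped or unwrapped) FASTA file into a
#' tibble.  RNA input is accepted: `U`/`u` is normalised to `T` and the record
#' is flagged in `is_rna`.  Record ids must be unique; letters outside
#' `A`, `C`, `G`, `T`, `U` (any case) are rejected with the offending symbol
#' named.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character), `seq` (character, upper-case
#'   DNA alphabet) and `is_rna` (logical: the record contained `U`).  Record
#'   order is preserved.  An empty file yields a zero-row tibble.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "GCUU"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("Cannot parse FASTA file '", path, "': ",
                   conditionMessage(e)))
    }
  )
  if (length(set) == 0) {
    return(tibble(id = character(), seq = character(), is_rna = logical()))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sequence id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  raw <- toupper(as.character(set))
  is_rna <- grepl("U", raw, fixed = TRUE)
  seqs <- chartr("U", "T", raw)
  bad <- lapply(strsplit(seqs, ""), function(x) setdiff(unique(x), VALID_BASES))
  offending <- unique(unlist(bad))
  if (length(offending) > 0) {
    abort(paste0("Non-IUPAC / unsupported letter(s) in FASTA: ",
                 paste(offending, collapse = ", "),
                 " (only A, C, G, T, U are accepted)"))
  }
  tibble(id = unname(ids), seq = unname(seqs), is_rna = unname(is_rna))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A data frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width (nucleotides per line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(seqs$seq)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param seq A DNA string (character scalar).
#' @return The reverse complement, same alphabet.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGT", "TGCA", vapply(strsplit(seq, ""), function(x) {
    paste(rev(x), collapse = "")
  }, character(1)))
}

.norm_dna <- function(seq) {
  chartr("U", "T", toupper(seq))
}

.check_dna <- function(seq) {
  seq <- .norm_dna(seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), VALID_BASES)
  if (length(bad) > 0) {
    abort(paste0("Invalid nucleotide letter(s): ", paste(bad, collapse = ", ")))
  }
  seq
}

#' Translate a coding sequence
#'
#' Translates `seq` from a 0-based `start` offset with the standard genetic
#' code.  A trailing partial codon is dropped.  With
#' `stop_policy = "truncate_at_stop"` the returned protein ends before the
#' first stop codon; with `"read_through"` stops are emitted as `*` and
#' translation continues to the end of the sequence.
#'
#' @param seq DNA (or RNA) string; `U` is normalised to `T`.
#' @param start 0-based offset of the first codon.
#' @param stop_policy `"truncate_at_stop"` (default) or `"read_through"`.
#' @return Amino-acid string (single-letter code; `*` marks stops under
#'   `"read_through"`).
#' @examples
#' translate_cds("ATGAAATAA")            # "MK"
#' translate_cds("ATGAAATAA", stop_policy = "read_through")  # "MK*"
#' @export
translate_cds <- function(seq, start = 0L,
                          stop_policy = c("truncate_at_stop", "read_through")) {
  stop_policy <- match.arg(stop_policy)
  seq <- .check_dna(seq)
  n <- nchar(seq)
  if (start < 0 || start > n) {
    abort(paste0("start (", start, ") outside sequence of length ", n))
  }
  sub <- substr(seq, start + 1L, n)
  ncod <- nchar(sub) %/% 3L
  if (ncod == 0) return("")
  codons <- substring(sub, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (stop_policy == "truncate_at_stop") {
    stop_at <- which(aa == "*")
    if (length(stop_at) > 0) {
      aa <- aa[seq_len(stop_at[1] - 1L)]
    }
  }
  paste(aa, collapse = "")
}

.codon_is_stop <- function(codon) {
  codon %in% c("TAA", "TAG", "TGA")
}

#' Find open reading frames
#'
#' Scans all three frames of the given strand.  With `require_atg = TRUE` an
#' ORF runs from the first `ATG` of a stop-delimited segment to the stop;
#' with `require_atg = FALSE` ORFs are stop-to-stop segments.  Coordinates
#' are 0-based half-open and include the terminal stop codon when present,
#' so `(end - start)` is always a multiple of three and the protein length is
#' `(end - start)/3`, minus one when `has_terminal_stop`.
#'
#' @param seq DNA string.
#' @param min_aa Minimum protein length (amino acids, excluding the stop).
#' @param require_atg Require an ATG start codon?
#' @return Tibble with columns `start`, `end`, `frame` (0, 1 or 2), `aa_seq`,
#'   `has_terminal_stop`, sorted by `start`.
#' @examples
#' find_orfs("ATGAAATAA", min_aa = 2, require_atg = TRUE)
#' @export
find_orfs <- function(seq, min_aa = 1L, require_atg = FALSE) {
  stopifnot(min_aa >= 1)
  seq <- .check_dna(seq)
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod <= 0) next
    codons <- substring(seq, frame + 3L * seq_len(ncod) - 2L,
                        frame + 3L * seq_len(ncod))
    is_stop <- .codon_is_stop(codons)
    seg_id <- cumsum(c(0L, utils::head(is_stop, -1L)))
    for (sid in unique(seg_id)) {
      idx <- which(seg_id == sid)
      stop_i <- idx[is_stop[idx]]
      coding <- setdiff(idx, stop_i)
      if (require_atg) {
        atg <- coding[codons[coding] == "ATG"]
        if (length(atg) == 0) next
        coding <- coding[coding >= atg[1]]
      }
      if (length(coding) < min_aa) next
      first <- min(coding)
      has_stop <- length(stop_i) > 0
      last <- if (has_stop) stop_i[1] else max(coding)
      start <- frame + 3L * (first - 1L)
      end <- frame + 3L * last
      out[[length(out) + 1L]] <- tibble(
        start = start, end = end, frame = frame,
        aa_seq = paste(Biostrings::GENETIC_CODE[codons[coding]], collapse = ""),
        has_terminal_stop = has_stop
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(), frame = integer(),
                  aa_seq = character(), has_terminal_stop = logical()))
  }
  bind_rows(out) %>% arrange(.data$start, .data$frame)
}

#' Average and monoisotopic amino-acid residue masses
#'
#' Residue (not free amino acid) masses in Daltons; the mass of a peptide is
#' the sum of its residue masses plus one water.
#'
#' @param type `"average"` (default, matches gel-derived kDa estimates) or
#'   `"monoisotopic"`.
#' @return Named numeric vector of residue masses with an attribute
#'   `water_mass`.
#' @export
amino_acid_masses <- function(type = c("average", "monoisotopic")) {
  type <- match.arg(type)
  avg <- c(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
  )
  mono <- c(
    A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
    E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
    L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
    S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
  )
  masses <- if (type == "average") avg else mono
  attr(masses, "water_mass") <- if (type == "average") 18.0153 else 18.010565
  masses
}

#' Molecular mass of a protein
#'
#' Sum of residue masses plus one water.  The empty string returns the mass
#' of water.
#'
#' @param aa_seq Amino-acid string (single-letter code, no stops).
#' @param type Passed to [amino_acid_masses()].
#' @return Mass in Daltons.
#' @examples
#' protein_mass("GG")   # 132.12 Da
#' @export
protein_mass <- function(aa_seq, type = c("average", "monoisotopic")) {
  masses <- amino_acid_masses(match.arg(type))
  if (nchar(aa_seq) == 0) return(attr(masses, "water_mass"))
  letters <- strsplit(aa_seq, "")[[1]]
  unknown <- setdiff(unique(letters), names(masses))
  if (length(unknown) > 0) {
    abort(paste0("Unknown amino-acid letter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  sum(masses[letters]) + attr(masses, "water_mass")
}
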