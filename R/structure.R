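# Stimulatory-element prediction: best single stem-loop and best H-type
# pseudoknot downstream of a slippery site, by exhaustive enumeration under a
# transparent pair-scoring scheme (full nearest-neighbor thermodynamics is
# deliberately out of scope; the search is exact and oracle-checkable).

#' Search bounds and scoring for structure prediction
#'
#' Defaults: stems of 3-12 pairs, loops up to 30 nt, at most 2 one-sided
#' bulges of up to 5 nt per stem; pair scores G.C = 3, A.U = 2, G.U = 1 with a
#' per-bulge penalty of `2 + 0.5/nt`; structures scoring below `min_score`
#' (default 12) are discarded.
#'
#' @param min_stem,max_stem Stem size range (base pairs).
#' @param max_loop Maximum loop length (nt).
#' @param max_bulges Maximum number of bulges per stem (at most 2).
#' @param max_bulge_len Maximum bulge length (nt).
#' @param min_hairpin_loop Minimum hairpin loop (nt) for single stems.
#' @param min_l1,min_l3 Minimum pseudoknot loop-1 and loop-3 lengths (nt).
#' @param min_score Acceptance threshold on the structure score.
#' @param score_gc,score_au,score_gu Per-pair scores.
#' @param allow_gu Allow G.U wobble pairs in stems.
#' @param bulge_open,bulge_per_nt Bulge penalty: `bulge_open +
#'   bulge_per_nt * length`.
#' @param max_window Maximum window length accepted by the exhaustive search.
#' @return A list of class `prf_bounds`.
#' @export
structure_bounds <- function(min_stem = 3L, max_stem = 12L, max_loop = 30L,
                             max_bulges = 2L, max_bulge_len = 5L,
                             min_hairpin_loop = 3L, min_l1 = 0L, min_l3 = 0L,
                             min_score = 12, score_gc = 3, score_au = 2,
                             score_gu = 1, allow_gu = TRUE, bulge_open = 2,
                             bulge_per_nt = 0.5, max_window = 120L) {
  stopifnot(min_stem >= 1, max_stem >= min_stem, max_bulges <= 2L,
            max_bulges >= 0L, max_bulge_len >= 1L, max_window >= 1L)
  structure(list(
    min_stem = as.integer(min_stem), max_stem = as.integer(max_stem),
    max_loop = as.integer(max_loop), max_bulges = as.integer(max_bulges),
    max_bulge_len = as.integer(max_bulge_len),
    min_hairpin_loop = as.integer(min_hairpin_loop),
    min_l1 = as.integer(min_l1), min_l3 = as.integer(min_l3),
    min_score = min_score, score_gc = score_gc, score_au = score_au,
    score_gu = score_gu, allow_gu = allow_gu, bulge_open = bulge_open,
    bulge_per_nt = bulge_per_nt, max_window = as.integer(max_window)
  ), class = "prf_bounds")
}

.encode_dna <- function(seq) {
  codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  unname(codes[strsplit(seq, "")[[1]]])
}

.stem_bulges <- function(pairs) {
  # pairs: tibble pos5 (ascending), pos3 (descending); gaps inside either
  # strand are bulges
  out <- list()
  l <- pairs$pos5
  r <- rev(pairs$pos3)  # ascending
  dl <- diff(l)
  for (k in which(dl > 1)) {
    out[[length(out) + 1L]] <- tibble(side = "left", start = l[k] + 1L,
                                      length = dl[k] - 1L)
  }
  dr <- diff(r)
  for (k in which(dr > 1)) {
    out[[length(out) + 1L]] <- tibble(side = "right", start = r[k] + 1L,
                                      length = dr[k] - 1L)
  }
  if (length(out) == 0) {
    return(tibble(side = character(), start = integer(), length = integer()))
  }
  bind_rows(out)
}

.new_stem <- function(pair_mat, seq, offset, score) {
  pairs <- tibble(pos5 = pair_mat[, 1] + offset, pos3 = pair_mat[, 2] + offset)
  pairs <- arrange(pairs, .data$pos5)
  structure(list(pairs = pairs, bulges = .stem_bulges(pairs),
                 score = score, seq = seq, offset = offset),
            class = "prf_stem")
}

#' @export
print.prf_stem <- function(x, ...) {
  cat("Stem: ", nrow(x$pairs), " pairs, ", sum(x$bulges$length),
      " bulged nt, score ", format(x$score), "\n", sep = "")
  invisible(x)
}

#' @export
print.prf_pseudoknot <- function(x, ...) {
  cat("H-type pseudoknot, score ", format(x$score), "\n", sep = "")
  cat(" stem1: ", nrow(x$stem1$pairs), " pairs (", sum(x$stem1$bulges$length),
      " bulged nt); stem2: ", nrow(x$stem2$pairs), " pairs; loops ",
      paste(x$loops, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Predict the best single stem-loop in a window
#'
#' Exhaustive search for the maximum-score stem (with up to
#' `bounds$max_bulges` one-sided bulges) whose two strands enclose a hairpin
#' loop of at least `bounds$min_hairpin_loop` nt.  Deterministic tie-break:
#' higher score, then more pairs, then 5'-most stem.
#'
#' @param window DNA/RNA string (at most `bounds$max_window` nt).
#' @param bounds A [structure_bounds()] object.
#' @param offset 0-based coordinate of the window's first base in the parent
#'   sequence; all reported coordinates are parent coordinates.
#' @return A `prf_stem` object, or `NULL` when no stem reaches
#'   `bounds$min_score`.
#' @examples
#' predict_hairpin("GGGGAAAACCCC", structure_bounds(min_score = 0))
#' @export
predict_hairpin <- function(window, bounds = structure_bounds(), offset = 0L) {
  window <- .check_dna(window)
  n <- nchar(window)
  if (n > bounds$max_window) {
    abort(paste0("Window of ", n, " nt exceeds max_window = ",
                 bounds$max_window, "; use a smaller window"))
  }
  if (n < 2 * bounds$min_stem + bounds$min_hairpin_loop) return(NULL)
  res <- cpp_best_hairpin(.encode_dna(window), unclass(bounds))
  if (!res$found || res$score < bounds$min_score) return(NULL)
  .new_stem(res$pairs, window, as.integer(offset), res$score)
}

#' Predict the best H-type pseudoknot in a window
#'
#' Exhaustive search over all pairs of crossing stems
#' (`stem1.left < stem2.left < stem1.right < stem2.right`) within the bounds;
#' the score of a pseudoknot is the sum of its two stem scores.  Deterministic
#' tie-break: higher score, then longer stem1, then 5'-most stem1, then
#' 5'-most stem2.
#'
#' @inheritParams predict_hairpin
#' @return A `prf_pseudoknot` object (fields `stem1`, `stem2`, `loops` =
#'   L1/L2/L3 lengths, `score`, `is_pseudoknot = TRUE`), or `NULL` when no
#'   crossing structure reaches `bounds$min_score`.
#' @export
predict_pseudoknot <- function(window, bounds = structure_bounds(),
                               offset = 0L) {
  window <- .check_dna(window)
  n <- nchar(window)
  if (n > bounds$max_window) {
    abort(paste0("Window of ", n, " nt exceeds max_window = ",
                 bounds$max_window, "; use a smaller window"))
  }
  if (n < 4 * bounds$min_stem) return(NULL)
  res <- cpp_best_pseudoknot(.encode_dna(window), unclass(bounds))
  if (!res$found || res$score < bounds$min_score) return(NULL)
  structure(list(
    stem1 = .new_stem(res$stem1_pairs, window, as.integer(offset),
                      res$stem1_score),
    stem2 = .new_stem(res$stem2_pairs, window, as.integer(offset),
                      res$stem2_score),
    loops = res$loops, score = res$score, is_pseudoknot = TRUE,
    seq = window, offset = as.integer(offset)
  ), class = "prf_pseudoknot")
}

#' Recompute the score of a predicted structure
#'
#' Applies the declared scoring function (per-pair scores minus bulge
#' penalties) to the pairs of a `prf_stem` or `prf_pseudoknot`, from scratch;
#' used to verify that reported scores are recomputable.
#'
#' @param x A `prf_stem` or `prf_pseudoknot`.
#' @param seq The parent sequence the coordinates refer to (defaults to the
#'   window stored in the object, with its offset).
#' @param bounds The [structure_bounds()] used for prediction.
#' @return Numeric score.
#' @export
score_structure <- function(x, seq = NULL, bounds = structure_bounds()) {
  if (inherits(x, "prf_pseudoknot")) {
    return(score_structure(x$stem1, seq, bounds) +
             score_structure(x$stem2, seq, bounds))
  }
  stopifnot(inherits(x, "prf_stem"))
  if (is.null(seq)) {
    seq <- x$seq
    shift <- x$offset
  } else {
    seq <- .check_dna(seq)
    shift <- 0L
  }
  base_at <- function(pos) substr(seq, pos - shift + 1L, pos - shift + 1L)
  sc <- 0
  for (k in seq_len(nrow(x$pairs))) {
    a <- base_at(x$pairs$pos5[k])
    b <- base_at(x$pairs$pos3[k])
    duo <- paste0(a, b)
    sc <- sc + if (duo %in% c("GC", "CG")) bounds$score_gc
    else if (duo %in% c("AT", "TA")) bounds$score_au
    else if (duo %in% c("GT", "TG")) bounds$score_gu
    else NA_real_
  }
  for (k in seq_len(nrow(x$bulges))) {
    sc <- sc - bounds$bulge_open - bounds$bulge_per_nt * x$bulges$length[k]
  }
  sc
}

#' Dot-bracket string for a predicted structure
#'
#' Stem-1 pairs are written `(`/`)`, stem-2 pairs `[`/`]`; unpaired window
#' positions are dots.
#'
#' @param x A `prf_stem` or `prf_pseudoknot`.
#' @return A string as long as the prediction window.
#' @export
dot_bracket <- function(x) {
  if (inherits(x, "prf_stem")) {
    n <- nchar(x$seq)
    out <- rep(".", n)
    out[x$pairs$pos5 - x$offset + 1L] <- "("
    out[x$pairs$pos3 - x$offset + 1L] <- ")"
    return(paste(out, collapse = ""))
  }
  stopifnot(inherits(x, "prf_pseudoknot"))
  n <- nchar(x$seq)
  out <- rep(".", n)
  out[x$stem1$pairs$pos5 - x$offset + 1L] <- "("
  out[x$stem1$pairs$pos3 - x$offset + 1L] <- ")"
  out[x$stem2$pairs$pos5 - x$offset + 1L] <- "["
  out[x$stem2$pairs$pos3 - x$offset + 1L] <- "]"
  paste(out, collapse = "")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a predicted structure into a pair table
#'
#' @param x A `prf_pseudoknot` or `prf_stem`.
#' @param ... Unused.
#' @return Tibble with columns `stem` (1 or 2), `pos5`, `pos3` (0-based,
#'   parent coordinates).
#' @export
tidy.prf_pseudoknot <- function(x, ...) {
  bind_rows(
    mutate(x$stem1$pairs, stem = 1L, .before = 1),
    mutate(x$stem2$pairs, stem = 2L, .before = 1)
  )
}

#' @rdname tidy.prf_pseudoknot
#' @export
tidy.prf_stem <- function(x, ...) {
  mutate(x$pairs, stem = 1L, .before = 1)
}

#' Fold the window downstream of a slippery site
#'
#' Extracts the search window starting `min_spacer` nt after the heptamer
#' (the first `min_spacer` bases are kept unpaired: the shortest spacers
#' observed in functional -1 PRF cassettes are 2 nt, and bases closer to the
#' decoding site are occupied by the ribosome) and predicts both the best
#' hairpin and the best pseudoknot.
#'
#' @param seq Full cassette sequence.
#' @param site One-row site tibble ([scan_slippery()] row).
#' @param bounds [structure_bounds()].
#' @param min_spacer Minimum unpaired spacer after the heptamer (nt).
#' @param window Search window length (nt) after the spacer floor.
#' @return List with elements `pseudoknot` and `hairpin` (either may be
#'   `NULL`), both in parent coordinates.
#' @export
fold_downstream <- function(seq, site, bounds = structure_bounds(),
                            min_spacer = 2L, window = 80L) {
  seq <- .check_dna(seq)
  from <- site$start + 7L + as.integer(min_spacer)
  to <- min(nchar(seq), from + as.integer(window))
  if (from >= to) {
    return(list(pseudoknot = NULL, hairpin = NULL))
  }
  win <- substr(seq, from + 1L, to)
  list(
    pseudoknot = predict_pseudoknot(win, bounds, offset = from),
    hairpin = predict_hairpin(win, bounds, offset = from)
  )
}

#' Cassette features of a slippery site plus stimulatory structure
#'
#' * `spacer_nt`: unpaired nucleotides between the heptamer's 3' end and the
#'   first paired base of stem 1;
#' * `stem1_bulge_nt`: total bulged nucleotides within stem 1;
#' * `stem1_base_gc_run`: contiguous G.C/C.G pairs at the base (spacer-
#'   proximal end) of stem 1.
#'
#' @param seq Cassette sequence (used for the G.C run).
#' @param site One-row slippery-site tibble.
#' @param structure A `prf_pseudoknot` or `prf_stem` downstream of the site.
#' @return One-row tibble with the three features.
#' @export
cassette_features <- function(seq, site, structure) {
  seq <- .check_dna(seq)
  stem1 <- if (inherits(structure, "prf_pseudoknot")) structure$stem1
  else structure
  stopifnot(inherits(stem1, "prf_stem"))
  first_paired <- min(stem1$pairs$pos5)
  hept_end <- site$start + 7L
  if (first_paired < hept_end) {
    abort("Structure lies upstream of (or overlaps) the slippery heptamer")
  }
  base_at <- function(pos) substr(seq, pos + 1L, pos + 1L)
  gc_run <- 0L
  for (k in seq_len(nrow(stem1$pairs))) {
    duo <- paste0(base_at(stem1$pairs$pos5[k]), base_at(stem1$pairs$pos3[k]))
    if (duo %in% c("GC", "CG")) gc_run <- gc_run + 1L else break
  }
  tibble(
    spacer_nt = first_paired - hept_end,
    stem1_bulge_nt = sum(stem1$bulges$length),
    stem1_base_gc_run = gc_run
  )
}

#' Scan sequences for complete frameshift cassettes
#'
#' For each sequence: find slippery sites ([scan_slippery()]), fold the
#' downstream window ([fold_downstream()]), and compute cassette features for
#' the best structure (the pseudoknot when one passes the score threshold,
#' otherwise the hairpin).
#'
#' @param seqs Data frame of sequences (`id`, `seq`) or a single string.
#' @param mode,shift,table Passed to [scan_slippery()].
#' @param bounds,min_spacer,window Passed to [fold_downstream()].
#' @return Tibble with one row per site: the site columns plus
#'   `structure_type` (`"pseudoknot"`, `"hairpin"` or `NA`), `pk_score`,
#'   `hp_score`, `spacer_nt`, `stem1_bulge_nt`, `stem1_base_gc_run`,
#'   `dot_bracket` and a `structure` list-column.
#' @export
scan_cassette <- function(seqs, mode = "relaxed", shift = -1L,
                          table = anticodon_table(),
                          bounds = structure_bounds(), min_spacer = 2L,
                          window = 80L) {
  if (is.character(seqs)) seqs <- tibble(id = "seq", seq = seqs)
  sites <- scan_slippery(seqs, mode = mode, shift = shift, table = table)
  if (nrow(sites) == 0) {
    return(mutate(sites, structure_type = character(), pk_score = numeric(),
                  hp_score = numeric(), spacer_nt = integer(),
                  stem1_bulge_nt = integer(), stem1_base_gc_run = integer(),
                  dot_bracket = character(), structure = list()))
  }
  extra <- purrr::map_dfr(seq_len(nrow(sites)), function(k) {
    site <- sites[k, ]
    seq <- seqs$seq[seqs$id == site$id][1]
    seq <- .check_dna(seq)
    folds <- fold_downstream(seq, site, bounds, min_spacer, window)
    best <- if (!is.null(folds$pseudoknot)) folds$pseudoknot else folds$hairpin
    if (is.null(best)) {
      return(tibble(structure_type = NA_character_, pk_score = NA_real_,
                    hp_score = NA_real_, spacer_nt = NA_integer_,
                    stem1_bulge_nt = NA_integer_,
                    stem1_base_gc_run = NA_integer_,
                    dot_bracket = NA_character_, structure = list(NULL)))
    }
    feats <- cassette_features(seq, site, best)
    tibble(
      structure_type = if (inherits(best, "prf_pseudoknot")) "pseudoknot"
      else "hairpin",
      pk_score = if (is.null(folds$pseudoknot)) NA_real_ else
        folds$pseudoknot$score,
      hp_score = if (is.null(folds$hairpin)) NA_real_ else
        folds$hairpin$score,
      spacer_nt = feats$spacer_nt,
      stem1_bulge_nt = feats$stem1_bulge_nt,
      stem1_base_gc_run = feats$stem1_base_gc_run,
      dot_bracket = dot_bracket(best),
      structure = list(best)
    )
  })
  bind_cols(sites, extra)
}
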