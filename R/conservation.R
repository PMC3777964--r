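# Structure-aware conservation analysis of aligned frameshift cassettes and
# parsimony mapping of 3'-ORF presence on a species tree.

COMPATIBLE_PAIRS <- c("CG", "GC", "AT", "TA", "GT", "TG")

#' Treat pre-aligned sequences as a cassette alignment
#'
#' @param seqs Data frame with columns `id` and `seq` (equal-length rows,
#'   gaps as `-`).
#' @return The input as a tibble with class checks applied.
#' @export
as_cassette_alignment <- function(seqs) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  lens <- nchar(seqs$seq)
  if (length(unique(lens)) != 1) {
    abort("Aligned rows must all have the same length")
  }
  as_tibble(seqs[, c("id", "seq")])
}

.pairwise_global <- function(a, b, match = 2, mismatch = -1,
                             gap_open = 10, gap_extend = 0.5) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend
  )
  list(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
}

#' Align cassette sequences
#'
#' Global alignment with affine gap penalties: optimal pairwise
#' (Needleman-Wunsch, via Biostrings) for two sequences; deterministic
#' star-progressive alignment around the most central sequence (highest total
#' pairwise score, ties to input order) for more, with once-a-gap-always-a-gap
#' merging.  This is a convenience aligner: pre-computed alignments can be
#' passed through unchanged via [as_cassette_alignment()].
#'
#' @param seqs Data frame with columns `id`, `seq` (ungapped), at least two
#'   rows.
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Tibble `id`, `seq` of equal-length gapped rows, input order
#'   preserved.
#' @export
align_cassettes <- function(seqs, match = 2, mismatch = -1, gap_open = 10,
                            gap_extend = 0.5) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  if (nrow(seqs) == 0) abort("No sequences to align")
  if (any(grepl("-", seqs$seq, fixed = TRUE))) {
    return(as_cassette_alignment(seqs))
  }
  if (nrow(seqs) == 1) return(as_tibble(seqs[, c("id", "seq")]))
  raw <- unname(vapply(seqs$seq, .check_dna, character(1)))
  n <- length(raw)
  if (n == 2) {
    pa <- .pairwise_global(raw[1], raw[2], match, mismatch, gap_open,
                           gap_extend)
    return(tibble(id = seqs$id, seq = c(pa$a, pa$b)))
  }
  # choose the centre sequence: maximal total pairwise score
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- .pairwise_global(raw[i], raw[j], match, mismatch, gap_open,
                            gap_extend)$score
      scores[i, j] <- s
      scores[j, i] <- s
    }
  }
  centre <- which.max(rowSums(scores))
  master_centre <- raw[centre]          # gapped centre, grows as gaps appear
  rows <- list()
  rows[[centre]] <- raw[centre]
  for (k in setdiff(seq_len(n), centre)) {
    pa <- .pairwise_global(raw[centre], raw[k], match, mismatch, gap_open,
                           gap_extend)
    mc <- strsplit(master_centre, "")[[1]]
    c2 <- strsplit(pa$a, "")[[1]]
    s2 <- strsplit(pa$b, "")[[1]]
    # merge the two gapped versions of the centre
    out_new <- character(0)
    ins_master <- integer(0)   # columns to insert into existing rows
    i <- 1L
    j <- 1L
    col <- 0L
    while (i <= length(mc) || j <= length(c2)) {
      col <- col + 1L
      gm <- i <= length(mc) && mc[i] == "-"
      gc2 <- j <= length(c2) && c2[j] == "-"
      if (i <= length(mc) && j <= length(c2) && !gm && !gc2) {
        out_new <- c(out_new, s2[j]); i <- i + 1L; j <- j + 1L
      } else if (gm && gc2) {
        out_new <- c(out_new, s2[j]); i <- i + 1L; j <- j + 1L
      } else if (gm) {
        out_new <- c(out_new, "-"); i <- i + 1L
      } else if (gc2 || i > length(mc)) {
        out_new <- c(out_new, s2[j]); ins_master <- c(ins_master, col)
        j <- j + 1L
      } else {
        out_new <- c(out_new, "-"); i <- i + 1L
      }
    }
    if (length(ins_master) > 0) {
      for (r in seq_along(rows)) {
        if (is.null(rows[[r]])) next
        ch <- strsplit(rows[[r]], "")[[1]]
        for (pos in ins_master) ch <- append(ch, "-", after = pos - 1L)
        rows[[r]] <- paste(ch, collapse = "")
      }
      ch <- strsplit(master_centre, "")[[1]]
      for (pos in ins_master) ch <- append(ch, "-", after = pos - 1L)
      master_centre <- paste(ch, collapse = "")
    }
    rows[[k]] <- paste(out_new, collapse = "")
  }
  tibble(id = seqs$id, seq = unlist(rows[seq_len(n)]))
}

#' Base-pair compatibility statistics for a column pair
#'
#' For each requested pair of alignment columns, counts the distinct
#' compatible base-pair types (among C-G, G-C, A-U, U-A, G-U, U-G) observed
#' across rows, the rows whose two bases cannot pair, and the rows with a gap
#' in either column.
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param col_i,col_j 0-based column indices (vectors of equal length).
#' @return Tibble with one row per column pair: `col_i`, `col_j`,
#'   `n_pair_types`, `n_compatible`, `n_incompatible`, `n_gapped`.
#' @export
column_pair_stats <- function(aln, col_i, col_j) {
  stopifnot(length(col_i) == length(col_j))
  width <- nchar(aln$seq[1])
  if (any(col_i < 0 | col_i >= width | col_j < 0 | col_j >= width)) {
    abort("Column index outside the alignment")
  }
  purrr::map2_dfr(col_i, col_j, function(ci, cj) {
    a <- toupper(substr(aln$seq, ci + 1L, ci + 1L))
    b <- toupper(substr(aln$seq, cj + 1L, cj + 1L))
    gapped <- a == "-" | b == "-"
    duo <- paste0(chartr("U", "T", a), chartr("U", "T", b))[!gapped]
    compat <- duo %in% COMPATIBLE_PAIRS
    tibble(
      col_i = ci, col_j = cj,
      n_pair_types = length(unique(duo[compat])),
      n_compatible = sum(compat),
      n_incompatible = sum(!compat),
      n_gapped = sum(gapped)
    )
  })
}

#' Project a reference structure onto alignment columns
#'
#' Maps the (ungapped, 0-based) pair coordinates of a structure predicted on
#' the reference row to alignment column indices.
#'
#' @param aln Alignment tibble.
#' @param ref Id of the reference row.
#' @param structure `prf_pseudoknot` or `prf_stem` in reference coordinates.
#' @return Tibble `stem`, `pos5`, `pos3` (reference coordinates), `col5`,
#'   `col3` (0-based alignment columns).
#' @export
project_structure <- function(aln, ref, structure) {
  row <- aln$seq[aln$id == ref]
  if (length(row) != 1) abort(paste0("Reference row '", ref, "' not found"))
  chars <- strsplit(row, "")[[1]]
  map <- which(chars != "-") - 1L      # alignment column of each ref position
  pairs <- tidy(structure)
  mutate(pairs,
         col5 = map[.data$pos5 + 1L] ,
         col3 = map[.data$pos3 + 1L])
}

#' Find compensatory and disruptive substitutions in paired columns
#'
#' Compares every species row to the reference row at each paired column of
#' the reference structure.  A change is `compensatory` when both bases
#' changed and the new combination still pairs, `wobble_shift` when pairing
#' is preserved through a single-base change (which necessarily passes
#' through a G.U wobble), and `disruptive` when the bases can no longer pair.
#' Rows with a gap in either column are skipped.
#'
#' @inheritParams project_structure
#' @return Tibble `species`, `stem`, `col5`, `col3`, `ref_pair`, `obs_pair`,
#'   `class`.
#' @export
find_compensatory <- function(aln, ref, structure) {
  proj <- project_structure(aln, ref, structure)
  others <- aln$id[aln$id != ref]
  ref_row <- aln$seq[aln$id == ref]
  purrr::map_dfr(seq_len(nrow(proj)), function(k) {
    ci <- proj$col5[k]
    cj <- proj$col3[k]
    ra <- substr(ref_row, ci + 1L, ci + 1L)
    rb <- substr(ref_row, cj + 1L, cj + 1L)
    purrr::map_dfr(others, function(sp) {
      row <- aln$seq[aln$id == sp]
      xa <- substr(row, ci + 1L, ci + 1L)
      xb <- substr(row, cj + 1L, cj + 1L)
      if (xa == "-" || xb == "-") return(tibble())
      if (xa == ra && xb == rb) return(tibble())
      compat <- paste0(xa, xb) %in% COMPATIBLE_PAIRS
      cls <- if (!compat) "disruptive"
      else if (xa != ra && xb != rb) "compensatory"
      else "wobble_shift"
      tibble(species = sp, stem = proj$stem[k], col5 = ci, col3 = cj,
             ref_pair = paste0(ra, "-", rb), obs_pair = paste0(xa, "-", xb),
             class = cls)
    })
  })
}

#' Frame of a 3' ORF extension relative to the 5' ORF
#'
#' @param orf5,orf3 One-row ORF tibbles (as from [find_orfs()]).
#' @return `"-1"`, `"+1"` or `"in_frame"`.
#' @export
classify_extension_frame <- function(orf5, orf3) {
  res <- (orf3$frame - orf5$frame) %% 3L
  c("in_frame", "+1", "-1")[res + 1L]
}

#' Minimum-change parsimony mapping of a binary character on a tree
#'
#' Fitch/Hartigan parsimony for a `present`/`absent` character on a rooted
#' tree (multifurcations supported): a bottom-up pass computes the candidate
#' state sets and the minimum number of changes, a top-down pass assigns
#' states (the root takes `root_prefer` when ambiguous; a child keeps its
#' parent's state whenever compatible) and labels every change on an edge as
#' a `gain` (absent to present) or `loss`.
#'
#' @param tree An [ape::phylo] tree (rooted).
#' @param states Data frame with columns `species`, `state` (values
#'   `present`/`absent`), one row per tip.
#' @param root_prefer State preferred at the root when the reconstruction is
#'   ambiguous there (default `"absent"`, the outgroup condition).
#' @return Object of class `prf_fitch`: list with `tree`, `node_states`
#'   (states for all tips and internal nodes, in ape node order), `events`
#'   (tibble `parent`, `child`, `child_label`, `event`), `n_changes`.
#' @export
fitch_map <- function(tree, states, root_prefer = c("absent", "present")) {
  root_prefer <- match.arg(root_prefer)
  stopifnot(inherits(tree, "phylo"))
  # the node ape stores as root is used as the root; a basal multifurcation
  # (e.g. a star tree) is treated as a rooted polytomy
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, states$species)
  if (length(missing_tips) > 0) {
    abort(paste0("No character state for leaf/leaves: ",
                 paste(missing_tips, collapse = ", ")))
  }
  st <- states$state[match(tips, states$species)]
  if (!all(st %in% c("present", "absent"))) {
    abort("States must be 'present' or 'absent'")
  }
  ntip <- length(tips)
  nnode <- tree$Nnode
  total <- ntip + nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  # candidate sets as 2-bit masks: 1 = absent, 2 = present
  mask <- integer(total)
  mask[seq_len(ntip)] <- ifelse(st == "present", 2L, 1L)
  n_changes <- 0L
  # internal nodes ordered so every node follows all of its children: take
  # each parent at its last appearance in the postorder edge list
  parents <- tree$edge[ape::postorder(tree), 1]
  post <- rev(unique(rev(parents)))
  for (v in post) {
    ch <- kids[[as.character(v)]]
    votes_a <- sum(bitwAnd(mask[ch], 1L) > 0)
    votes_p <- sum(bitwAnd(mask[ch], 2L) > 0)
    m <- max(votes_a, votes_p)
    mask[v] <- (if (votes_a == m) 1L else 0L) + (if (votes_p == m) 2L else 0L)
    n_changes <- n_changes + length(ch) - m
  }
  # top-down assignment
  assign <- character(total)
  root <- ntip + 1L
  root_mask <- mask[root]
  prefer_bit <- if (root_prefer == "absent") 1L else 2L
  assign[root] <- if (bitwAnd(root_mask, prefer_bit) > 0) root_prefer
  else if (bitwAnd(root_mask, 1L) > 0) "absent" else "present"
  # cladewise edge order lists every parent before its descendants' edges
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(ord))) {
    par <- ord[e, 1]
    ch <- ord[e, 2]
    pbit <- if (assign[par] == "absent") 1L else 2L
    if (bitwAnd(mask[ch], pbit) > 0) {
      assign[ch] <- assign[par]
    } else {
      assign[ch] <- if (bitwAnd(mask[ch], 1L) > 0) "absent" else "present"
    }
  }
  events <- purrr::map_dfr(seq_len(nrow(tree$edge)), function(e) {
    par <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    if (assign[par] == assign[ch]) return(tibble())
    tibble(
      parent = par, child = ch,
      child_label = if (ch <= ntip) tips[ch] else paste0("node_", ch),
      event = if (assign[par] == "absent") "gain" else "loss"
    )
  })
  structure(list(tree = tree, node_states = assign, events = events,
                 n_changes = n_changes), class = "prf_fitch")
}

#' @export
print.prf_fitch <- function(x, ...) {
  cat("Parsimony character map: ", x$n_changes, " change(s); ",
      sum(x$events$event == "gain"), " gain(s), ",
      sum(x$events$event == "loss"), " loss(es)\n", sep = "")
  invisible(x)
}

#' Tidy the reconstructed character-change events
#'
#' @param x A `prf_fitch` object.
#' @param ... Unused.
#' @return The events tibble (`parent`, `child`, `child_label`, `event`).
#' @export
tidy.prf_fitch <- function(x, ...) {
  x$events
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a parsimony reconstruction
#'
#' @param x A `prf_fitch` object.
#' @param ... Unused.
#' @return Tibble with `n_changes`, `n_gains`, `n_losses`, `root_state`.
#' @export
glance.prf_fitch <- function(x, ...) {
  tibble(
    n_changes = x$n_changes,
    n_gains = sum(x$events$event == "gain"),
    n_losses = sum(x$events$event == "loss"),
    root_state = x$node_states[length(x$tree$tip.label) + 1L]
  )
}
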