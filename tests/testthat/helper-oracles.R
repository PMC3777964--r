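# Independent brute-force oracles used by the property tests.  These are
# deliberately written as naive enumerations, separate from the package's
# implementations.

PAIRS_WC <- c("GC", "CG", "AT", "TA")
PAIRS_ALL <- c(PAIRS_WC, "GT", "TG")

random_dna <- function(n, p_gc = 0.5) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(p_gc / 2, p_gc / 2, (1 - p_gc) / 2, (1 - p_gc) / 2)),
        collapse = "")
}

# --- ORF oracle -------------------------------------------------------------

oracle_orfs <- function(seq, min_aa, require_atg) {
  code <- Biostrings::GENETIC_CODE
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  rows <- list()
  for (frame in 0:2) {
    starts <- seq(frame, n - 3, by = 3)
    if (frame > n - 3) next
    codons <- vapply(starts, function(s) paste(chars[(s + 1):(s + 3)],
                                               collapse = ""), character(1))
    stops <- code[codons] == "*"
    seg_start <- 1L
    k <- 1L
    while (k <= length(codons) + 1L) {
      if (k > length(codons) || stops[k]) {
        idx <- if (seg_start <= k - 1L) seg_start:(k - 1L) else integer(0)
        if (require_atg && length(idx) > 0) {
          hit <- which(codons[idx] == "ATG")
          idx <- if (length(hit) > 0) idx[hit[1]:length(idx)] else integer(0)
        }
        if (length(idx) >= min_aa) {
          has_stop <- k <= length(codons)
          rows[[length(rows) + 1L]] <- data.frame(
            start = starts[idx[1]],
            end = if (has_stop) starts[k] + 3L else starts[idx[length(idx)]] +
              3L,
            frame = frame,
            aa_seq = paste(code[codons[idx]], collapse = ""),
            has_terminal_stop = has_stop
          )
        }
        seg_start <- k + 1L
      }
      k <- k + 1L
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      aa_seq = character(), has_terminal_stop = logical()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$frame), , drop = FALSE]
}

# --- stem / pseudoknot oracle ----------------------------------------------

# enumerate every stem as a growing list of pairs, extending pair-by-pair
# with optional one-sided gaps (bulges); returns a data.frame of stem
# summaries (footprints and score)
oracle_stems <- function(seq, b) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  pairable <- function(i, j) {
    duo <- paste0(chars[i + 1], chars[j + 1])
    duo %in% (if (b$allow_gu) PAIRS_ALL else PAIRS_WC)
  }
  pscore <- function(i, j) {
    duo <- paste0(chars[i + 1], chars[j + 1])
    if (duo %in% c("GC", "CG")) b$score_gc
    else if (duo %in% c("AT", "TA")) b$score_au
    else b$score_gu
  }
  acc <- list()
  emit <- function(pairs, nb, bnt) {
    sc <- sum(vapply(pairs, function(p) pscore(p[1], p[2]), numeric(1))) -
      nb * b$bulge_open - bnt * b$bulge_per_nt
    l <- vapply(pairs, `[`, integer(1), 1)
    r <- vapply(pairs, `[`, integer(1), 2)
    acc[[length(acc) + 1L]] <<- c(l0 = min(l), l1 = max(l), r0 = min(r),
                                  r1 = max(r), np = length(pairs),
                                  score = sc)
  }
  grow <- function(pairs, nb, bnt) {
    if (length(pairs) >= b$min_stem) emit(pairs, nb, bnt)
    if (length(pairs) >= b$max_stem) return()
    last <- pairs[[length(pairs)]]
    for (gl in 0:b$max_bulge_len) {
      for (gr in 0:b$max_bulge_len) {
        if (gl > 0 && gr > 0) next
        if ((gl > 0 || gr > 0) && nb >= b$max_bulges) next
        i2 <- last[1] + 1L + gl
        j2 <- last[2] - 1L - gr
        if (i2 >= j2) next
        if (!pairable(i2, j2)) next
        grow(c(pairs, list(c(i2, j2))), nb + (gl > 0 || gr > 0),
             bnt + gl + gr)
      }
    }
  }
  for (i in 0:(n - 2)) {
    for (j in (i + 2):(n - 1)) {
      if (j > n - 1) next
      if (pairable(i, j)) grow(list(c(i, j)), 0L, 0L)
    }
  }
  if (length(acc) == 0) return(NULL)
  as.data.frame(do.call(rbind, acc))
}

oracle_best_hairpin_score <- function(seq, b) {
  st <- oracle_stems(seq, b)
  if (is.null(st)) return(NA_real_)
  loop <- st$r0 - st$l1 - 1
  ok <- loop >= b$min_hairpin_loop & loop <= b$max_loop
  if (!any(ok)) return(NA_real_)
  max(st$score[ok])
}

oracle_best_pk_score <- function(seq, b) {
  st <- oracle_stems(seq, b)
  if (is.null(st) || nrow(st) < 2) return(NA_real_)
  best <- NA_real_
  for (a in seq_len(nrow(st))) {
    s1 <- st[a, ]
    L1 <- st$l0 - s1$l1 - 1
    L2 <- s1$r0 - st$l1 - 1
    L3 <- st$r0 - s1$r1 - 1
    ok <- L1 >= b$min_l1 & L2 >= 0 & L3 >= b$min_l3 &
      L1 <= b$max_loop & L2 <= b$max_loop & L3 <= b$max_loop
    if (!any(ok)) next
    tot <- s1$score + max(st$score[ok])
    if (is.na(best) || tot > best) best <- tot
  }
  best
}

# --- alignment oracle -------------------------------------------------------

# exhaustive global alignment score with affine gaps (Biostrings convention:
# each gap of length L costs gap_open + gap_extend * L)
oracle_align_score <- function(a, b, match = 2, mismatch = -1,
                               gap_open = 10, gap_extend = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, sc, in_gap) {
    # in_gap: 0 none, 1 gap in a (consuming b), 2 gap in b (consuming a)
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, sc)
      return()
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1,
          sc + if (ca[i] == cb[j]) match else mismatch, 0L)
    }
    if (j <= length(cb)) {
      rec(i, j + 1, sc - gap_extend - if (in_gap == 1L) 0 else gap_open, 1L)
    }
    if (i <= length(ca)) {
      rec(i + 1, j, sc - gap_extend - if (in_gap == 2L) 0 else gap_open, 2L)
    }
  }
  rec(1L, 1L, 0, 0L)
  best
}

score_alignment_affine <- function(a, b, match = 2, mismatch = -1,
                                   gap_open = 10, gap_extend = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sc <- 0
  gap_a <- FALSE
  gap_b <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      sc <- sc - gap_extend - if (gap_a) 0 else gap_open
      gap_a <- TRUE
      gap_b <- FALSE
    } else if (cb[k] == "-") {
      sc <- sc - gap_extend - if (gap_b) 0 else gap_open
      gap_b <- TRUE
      gap_a <- FALSE
    } else {
      sc <- sc + if (ca[k] == cb[k]) match else mismatch
      gap_a <- FALSE
      gap_b <- FALSE
    }
  }
  sc
}

# --- parsimony oracle -------------------------------------------------------

oracle_fitch_count <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  leaf <- states$state[match(tree$tip.label, states$species)]
  grid <- expand.grid(rep(list(c("absent", "present")), nnode),
                      stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign <- c(leaf, unlist(grid[g, ], use.names = FALSE))
    ch <- sum(assign[tree$edge[, 1]] != assign[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# --- Mann-Whitney oracle ----------------------------------------------------

# U from its direct definition (count of x > y pairs, halves for ties), and
# the exact two-sided p by enumeration over labelings
oracle_mw <- function(x, y) {
  u_direct <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  centre <- nx * ny / 2
  u_obs <- u_direct(x, y)
  labelings <- utils::combn(nx + ny, nx)
  devs <- apply(labelings, 2, function(idx) {
    abs(u_direct(pooled[idx], pooled[-idx]) - centre)
  })
  list(U = u_obs, p = mean(devs >= abs(u_obs - centre) - 1e-9))
}

# --- codon-anticodon oracle -------------------------------------------------

# manual antiparallel alignment of the decoding tRNA's anticodon to a codon,
# returning whether positions 1 and 2 re-pair without mismatch
oracle_repairs_ok <- function(codon_from, codon_to,
                              table = prfscan::anticodon_table()) {
  ac <- strsplit(table$anticodon[table$codon == codon_from], "")[[1]]
  ct <- chartr("T", "U", strsplit(codon_to, "")[[1]])
  ok_one <- function(cb, ab) {
    if (ab == "I") return(cb %in% c("U", "C", "A"))
    paste0(cb, ab) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  ok_one(ct[1], ac[3]) && ok_one(ct[2], ac[2])
}
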