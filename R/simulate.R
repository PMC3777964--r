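# Seeded generators for every input the pipeline consumes: frameshift
# cassettes with known truth, ortholog families evolved on a tree with
# compensatory stem substitutions and 3'-ORF losses, and dual-reporter
# measurements around a known efficiency.

NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA"))

#' Specification of a synthetic frameshift cassette
#'
#' The defaults mirror the *PaYIP3* cassette anatomy: the `TTTTTCC` heptamer,
#' a 2-nt spacer, a 10-pair stem 1 carrying a 3-nt bulge, a 5-pair stem 2 and
#' loops of 2/2/7 nt.  `orf5_aa` is the number of codons of the upstream ORF
#' up to and including the codon that ends with the heptamer's first base
#' (desk-scale default 30; the natural gene is longer), and `orf3_aa` the
#' number of codons translated in the shifted register after the slip.
#'
#' @param heptamer 7-nt slippery heptamer (DNA).
#' @param spacer_nt Unpaired nucleotides between heptamer and stem 1
#'   (at least 2).
#' @param stem1_pairs,stem2_pairs Stem sizes (base pairs).
#' @param stem1_bulge_nt Bulge length inside stem 1 (on its 3' strand).
#' @param bulge_after Pairs between the base of stem 1 and its bulge.
#' @param loop_lens Lengths of loops L1, L2, L3 (nt).
#' @param orf5_aa,orf3_aa ORF sizes (codons), see above.
#' @param shift `-1` or `+1`.
#' @param seed RNG seed (generation is bit-reproducible given the seed).
#' @return List of class `cassette_spec`.
#' @export
cassette_spec <- function(heptamer = "TTTTTCC", spacer_nt = 2L,
                          stem1_pairs = 10L, stem2_pairs = 5L,
                          stem1_bulge_nt = 3L, bulge_after = 4L,
                          loop_lens = c(2L, 2L, 7L), orf5_aa = 30L,
                          orf3_aa = 25L, shift = -1L, seed = 1L) {
  heptamer <- .check_dna(heptamer)
  if (nchar(heptamer) != 7) abort("heptamer must be 7 nt")
  if (spacer_nt < 2) {
    abort("spacer_nt must be >= 2 (the cassette-level search keeps the ",
          "first 2 nt after the heptamer unpaired)")
  }
  stopifnot(stem1_pairs >= 3, stem2_pairs >= 3, stem1_bulge_nt >= 0,
            bulge_after >= 1, bulge_after < stem1_pairs,
            length(loop_lens) == 3, orf5_aa >= 3, shift %in% c(-1L, 1L))
  struct_len <- spacer_nt + 2L * stem1_pairs + stem1_bulge_nt +
    2L * stem2_pairs + sum(loop_lens)
  min_orf3 <- ceiling((struct_len + 1L - shift) / 3)
  if (orf3_aa < min_orf3) {
    abort(paste0("orf3_aa = ", orf3_aa, " cannot reach past the planted ",
                 "structure; need at least ", min_orf3,
                 " codons for this geometry"))
  }
  structure(list(
    heptamer = heptamer, spacer_nt = as.integer(spacer_nt),
    stem1_pairs = as.integer(stem1_pairs),
    stem2_pairs = as.integer(stem2_pairs),
    stem1_bulge_nt = as.integer(stem1_bulge_nt),
    bulge_after = as.integer(bulge_after),
    loop_lens = as.integer(loop_lens), orf5_aa = as.integer(orf5_aa),
    orf3_aa = as.integer(orf3_aa), shift = as.integer(shift),
    seed = as.integer(seed)
  ), class = "cassette_spec")
}

.rand_bases <- function(n, p_gc = 0.5) {
  if (n <= 0) return(character(0))
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(p_gc / 2, p_gc / 2, (1 - p_gc) / 2, (1 - p_gc) / 2))
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.assemble_cassette <- function(spec) {
  # one random assembly attempt; returns list(seq, truth-skeleton) or NULL
  # when a constraint cannot be repaired locally
  a <- spec$orf5_aa
  p <- 3L * a - 1L
  hept <- strsplit(spec$heptamer, "")[[1]]
  # prefix: ATG + fillers + a codon ending with the heptamer's first base
  fillers <- sample(NON_STOP_CODONS, a - 2L, replace = TRUE)
  last_cands <- NON_STOP_CODONS[substr(NON_STOP_CODONS, 3, 3) == hept[1]]
  prefix <- c("ATG", fillers, sample(last_cands, 1L))
  s1l <- .rand_bases(spec$stem1_pairs, p_gc = 0.7)
  s2l <- .rand_bases(spec$stem2_pairs, p_gc = 0.7)
  cut <- spec$stem1_pairs - spec$bulge_after
  # an all-A bulge cannot slide into the neighbouring helix when the pairs
  # flanking it (left-strand positions cut and cut+1 from the top) avoid T
  if (spec$stem1_bulge_nt > 0) {
    flank <- c(spec$bulge_after, spec$bulge_after + 1L)
    s1l[flank] <- sample(c("G", "C"), length(flank), replace = TRUE)
  }
  bulge <- rep("A", spec$stem1_bulge_nt)
  s1r_pairs <- rev(unname(.complement[s1l]))   # 5'->3' right strand, no bulge
  s1r <- c(s1r_pairs[seq_len(cut)], bulge,
           s1r_pairs[seq(cut + 1L, length(s1r_pairs))])
  s2r <- rev(unname(.complement[s2l]))
  l1 <- .rand_bases(spec$loop_lens[1])
  l2 <- .rand_bases(spec$loop_lens[2])
  l3 <- .rand_bases(spec$loop_lens[3])
  spacer <- .rand_bases(spec$spacer_nt)
  resume <- p + 7L + spec$shift
  stop_start <- resume + 3L * spec$orf3_aa
  struct_chars <- c(spacer, s1l, l1, s2l, l2, s1r, l3, s2r)
  struct_end <- p + 7L + length(struct_chars)
  tail_len <- stop_start - struct_end
  tail <- .rand_bases(tail_len)
  chars <- c(strsplit(paste(prefix, collapse = ""), "")[[1]], hept[-1],
             struct_chars, tail, c("T", "A", "A"))
  # planted coordinates (0-based)
  s1l_start <- p + 7L + spec$spacer_nt
  l1_start <- s1l_start + spec$stem1_pairs
  s2l_start <- l1_start + spec$loop_lens[1]
  l2_start <- s2l_start + spec$stem2_pairs
  s1r_start <- l2_start + spec$loop_lens[2]
  s1r_end <- s1r_start + spec$stem1_pairs + spec$stem1_bulge_nt
  l3_start <- s1r_end
  s2r_start <- l3_start + spec$loop_lens[3]
  # block helix extension at every stem boundary: the bases just outside a
  # stem end are set to A (A cannot pair A, and the inside partners of these
  # positions are mostly G/C); all these positions are unconstrained filler
  blockers <- c(s1l_start - 1L, s1r_end,                 # stem1 outer
                l1_start, s1r_start - 1L,                # stem1 inner
                s2l_start - 1L, s2r_start + spec$stem2_pairs,  # stem2 outer
                s2l_start + spec$stem2_pairs, s2r_start - 1L)  # stem2 inner
  blockers <- blockers[blockers >= p + 7L & blockers < stop_start]
  chars[blockers + 1L] <- "A"
  n <- length(chars)
  free_pos <- setdiff(seq(p + 7L, n - 4L),
                      c(seq(s1l_start, l1_start - 1L),
                        seq(s2l_start, s2l_start + spec$stem2_pairs - 1L),
                        seq(s1r_start, s1r_end - 1L),
                        seq(s2r_start, s2r_start + spec$stem2_pairs - 1L)))
  # repair shifted-register stop codons between the slip and the planted stop
  for (pass in 1:3) {
    fixed_any <- FALSE
    for (cs in seq(resume, stop_start - 3L, by = 3L)) {
      codon <- paste(chars[(cs + 1L):(cs + 3L)], collapse = "")
      if (!.codon_is_stop(codon)) next
      editable <- intersect(cs:(cs + 2L), setdiff(free_pos, blockers))
      if (length(editable) == 0) return(NULL)
      pos <- editable[[sample.int(length(editable), 1L)]]
      chars[pos + 1L] <- "C"   # no stop codon contains C
      fixed_any <- TRUE
    }
    if (!fixed_any) break
  }
  seq <- paste(chars, collapse = "")
  right_positions <- seq(s1r_start, s1r_end - 1L)
  if (spec$stem1_bulge_nt > 0) {
    right_positions <- setdiff(right_positions,
                               seq(s1r_start + cut,
                                   length.out = spec$stem1_bulge_nt))
  }
  stem1 <- tibble(pos5 = seq(s1l_start, length.out = spec$stem1_pairs),
                  pos3 = rev(right_positions))
  stem2 <- tibble(pos5 = seq(s2l_start, length.out = spec$stem2_pairs),
                  pos3 = rev(seq(s2r_start, length.out = spec$stem2_pairs)))
  list(seq = seq, p = p, resume = resume, stop_start = stop_start,
       stem1 = stem1, stem2 = stem2)
}

.frame_codons <- function(seq, from, to) {
  # codons of the register starting at `from` (0-based), up to < to
  n <- (to - from) %/% 3L
  if (n <= 0) return(character(0))
  substring(seq, from + 3L * seq_len(n) - 2L, from + 3L * seq_len(n))
}

#' Generate a synthetic frameshift cassette with known truth
#'
#' Builds a sequence `[5' ORF][heptamer][spacer][pseudoknot][shifted-frame 3'
#' ORF]` realizing the requested geometry exactly.  Filler sequence is
#' GC-balanced uniform
#' i.i.d.; stem strands are planted by construction.  Each assembly is
#' validated: the planted heptamer must be the detected site, the planted
#' stems must be the unique argmax of the structure search, the ORF pair must
#' be the single detected pair, and the shifted register must be stop-free
#' from the slip to the planted stop; colliding fillers are resampled
#' (deterministically, within the seeded stream).
#'
#' @param spec A [cassette_spec()].
#' @param bounds Structure-search bounds used for the optimality re-check.
#' @param max_tries Resampling budget before giving up.
#' @return List with `seqs` (one-row tibble `id`, `seq`, `is_rna`) and
#'   `truth` (heptamer offset, planted stem pair tables, spacer/bulge
#'   features, ORF coordinates, fusion protein and its mass, slippage model).
#' @export
make_cassette <- function(spec, bounds = structure_bounds(),
                          max_tries = 400L) {
  stopifnot(inherits(spec, "cassette_spec"))
  withr::with_seed(spec$seed, {
    for (try in seq_len(max_tries)) {
      asm <- .assemble_cassette(spec)
      if (is.null(asm)) next
      seq <- asm$seq
      p <- asm$p
      n <- nchar(seq)
      # shifted register must be stop-free between slip and planted stop
      shift_cod <- .frame_codons(seq, asm$resume, asm$stop_start)
      if (any(.codon_is_stop(shift_cod))) next
      # planted stop must be the first stop of its register at/after resume
      if (!.codon_is_stop(substr(seq, asm$stop_start + 1L,
                                 asm$stop_start + 3L))) next
      # the zero frame must terminate after the heptamer and before the
      # planted stop
      zero_cod <- .frame_codons(seq, p + 7L, asm$stop_start)
      if (!any(.codon_is_stop(zero_cod))) next
      orf5_end <- p + 7L + 3L * which(.codon_is_stop(zero_cod))[1]
      # detection checks
      pairs <- find_orf_pairs(seq, min_aa5 = 10L, min_aa3 = 10L)
      pairs <- pairs[pairs$shift == spec$shift, ]
      if (nrow(pairs) != 1 || pairs$orf5_start != 0 ||
          pairs$orf5_end != orf5_end ||
          pairs$orf3_end != asm$stop_start + 3L) next
      site <- slippery_site(seq, p, shift = spec$shift)
      win_from <- p + 9L   # heptamer end + default 2-nt spacer floor
      win <- substr(seq, win_from + 1L, min(n, win_from + 80L))
      pk <- predict_pseudoknot(win, bounds, offset = win_from)
      if (is.null(pk)) next
      ok_pk <- identical(pk$stem1$pairs$pos5, asm$stem1$pos5) &&
        identical(pk$stem1$pairs$pos3, asm$stem1$pos3) &&
        identical(pk$stem2$pairs$pos5, asm$stem2$pos5) &&
        identical(pk$stem2$pairs$pos3, asm$stem2$pos3)
      if (!ok_pk) next
      # truth fusion, computed directly from the layout
      model <- classify_site(site)
      cut0 <- if (model == "single_P") p + 4L else p + 7L
      resume <- cut0 + spec$shift
      part5 <- translate_cds(substr(seq, 1L, cut0),
                             stop_policy = "read_through")
      part3 <- translate_cds(seq, start = resume)
      truth <- list(
        heptamer_start = p, heptamer = spec$heptamer, shift = spec$shift,
        model = model, spacer_nt = spec$spacer_nt,
        stem1_pairs = asm$stem1, stem2_pairs = asm$stem2,
        stem1_bulge_nt = spec$stem1_bulge_nt,
        orf5_start = 0L, orf5_end = orf5_end,
        orf3_end = asm$stop_start + 3L,
        fusion_aa = paste0(part5, part3),
        fusion_mass_da = protein_mass(paste0(part5, part3)),
        tries = try
      )
      return(list(
        seqs = tibble(id = paste0("cassette_seed", spec$seed), seq = seq,
                      is_rna = FALSE),
        truth = truth
      ))
    }
    abort(paste0("Could not realize the cassette spec in ", max_tries,
                 " attempts; relax the geometry (longer loops or ",
                 "lower-GC stems make collisions rarer)"))
  })
}

#' Generate an ortholog family of cassettes evolved on a tree
#'
#' Starting from a base cassette at the root, sequences evolve down the tree:
#' each planted stem pair mutates with probability `rate` per edge (a
#' compensatory double substitution to a different Watson-Crick pair with
#' probability `compensatory_fraction`, otherwise a disruptive single-base
#' change), and each unconstrained position mutates with probability `rate`.
#' The heptamer, start codon, 5'-ORF stop and planted shifted-frame stop are
#' protected, and mutations that would truncate either ORF are redrawn, so
#' that presence of the cassette remains detectable.  Leaves below
#' `loss_nodes` lose the 3' ORF (the sequence is truncated at the 5' ORF's
#' stop and stops evolving).
#'
#' @param tree A rooted [ape::phylo].
#' @param base_spec [cassette_spec()] of the ancestral cassette.
#' @param rate Per-edge, per-position (or per-pair) substitution probability.
#' @param compensatory_fraction Share of stem substitutions that preserve
#'   pairing.
#' @param loss_nodes Tip labels or internal node numbers whose subtrees lose
#'   the 3' ORF (the loss happens on the edge leading to the node).
#' @param seed RNG seed.
#' @return List: `seqs` (tibble of leaf sequences), `tree`, `states`
#'   (truth presence/absence per leaf), `ancestor` (tibble with the root
#'   cassette), `truth` (base-cassette truth plus `pair_changes`, the planted
#'   substitutions of every present leaf relative to the ancestor).
#' @export
make_family <- function(tree, base_spec = cassette_spec(), rate = 0.03,
                        compensatory_fraction = 1, loss_nodes = character(0),
                        seed = 1L) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 3)
  base <- make_cassette(base_spec)
  truth0 <- base$truth
  root_seq <- base$seqs$seq[1]
  n <- nchar(root_seq)
  pair_tab <- bind_rows(
    mutate(truth0$stem1_pairs, stem = 1L),
    mutate(truth0$stem2_pairs, stem = 2L)
  )
  protected <- c(0:2, seq(truth0$heptamer_start, truth0$heptamer_start + 6L),
                 seq(truth0$orf5_end - 3L, truth0$orf5_end - 1L),
                 seq(truth0$orf3_end - 3L, truth0$orf3_end - 1L))
  pair_positions <- c(pair_tab$pos5, pair_tab$pos3)
  free_pos <- setdiff(0:(n - 1L), c(protected, pair_positions))
  ntip <- length(tree$tip.label)
  loss_children <- integer(0)
  if (length(loss_nodes) > 0) {
    for (ln in loss_nodes) {
      if (is.character(ln) && ln %in% tree$tip.label) {
        loss_children <- c(loss_children, match(ln, tree$tip.label))
      } else if (is.numeric(ln)) {
        loss_children <- c(loss_children, as.integer(ln))
      } else {
        abort(paste0("Unknown loss node: ", ln))
      }
    }
  }
  wc_pairs <- c("GC", "CG", "AT", "TA")
  withr::with_seed(seed, {
    seqs <- vector("list", ntip + tree$Nnode)
    lost <- logical(ntip + tree$Nnode)
    seqs[[ntip + 1L]] <- root_seq
    changes <- list()
    ord <- ape::reorder.phylo(tree, "cladewise")$edge
    detect_ok <- function(s) {
      pr <- find_orf_pairs(s, min_aa5 = 10L, min_aa3 = 10L)
      pr <- pr[pr$shift == truth0$shift, ]
      nrow(pr) == 1 && pr$orf3_end == truth0$orf3_end
    }
    for (e in seq_len(nrow(ord))) {
      par <- ord[e, 1]
      ch <- ord[e, 2]
      if (lost[par] || ch %in% loss_children) {
        lost[ch] <- TRUE
        seqs[[ch]] <- substr(seqs[[par]], 1L, truth0$orf5_end)
        next
      }
      parent_seq <- seqs[[par]]
      for (attempt in 1:50) {
        chars <- strsplit(parent_seq, "")[[1]]
        edge_changes <- list()
        for (k in seq_len(nrow(pair_tab))) {
          if (stats::runif(1) >= rate) next
          i <- pair_tab$pos5[k] + 1L
          j <- pair_tab$pos3[k] + 1L
          from <- paste0(chars[i], chars[j])
          if (stats::runif(1) < compensatory_fraction) {
            cands <- wc_pairs[substr(wc_pairs, 1, 1) != chars[i] &
                                substr(wc_pairs, 2, 2) != chars[j]]
            to <- sample(cands, 1L)
            cls <- "compensatory"
          } else {
            bad <- setdiff(c("A", "C", "G", "T"), chars[i])
            bad <- bad[!paste0(bad, chars[j]) %in% COMPATIBLE_PAIRS]
            to <- paste0(sample(bad, 1L), chars[j])
            cls <- "disruptive"
          }
          chars[i] <- substr(to, 1, 1)
          chars[j] <- substr(to, 2, 2)
          edge_changes[[length(edge_changes) + 1L]] <-
            tibble(node = ch, col5 = pair_tab$pos5[k],
                   col3 = pair_tab$pos3[k], stem = pair_tab$stem[k],
                   from_pair = from, to_pair = to, class = cls)
        }
        mut_free <- free_pos[stats::runif(length(free_pos)) < rate]
        for (pos in mut_free) {
          chars[pos + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                            chars[pos + 1L]), 1L)
        }
        cand <- paste(chars, collapse = "")
        if (detect_ok(cand)) {
          seqs[[ch]] <- cand
          changes <- c(changes, edge_changes)
          break
        }
        if (attempt == 50L) seqs[[ch]] <- parent_seq
      }
    }
    leaf_seqs <- tibble(id = tree$tip.label,
                        seq = unlist(seqs[seq_len(ntip)]))
    states <- tibble(species = tree$tip.label,
                     state = ifelse(lost[seq_len(ntip)], "absent", "present"))
    # net per-leaf pair changes relative to the ancestor
    pair_changes <- purrr::map_dfr(which(!lost[seq_len(ntip)]), function(t) {
      s <- leaf_seqs$seq[t]
      purrr::map_dfr(seq_len(nrow(pair_tab)), function(k) {
        i <- pair_tab$pos5[k] + 1L
        j <- pair_tab$pos3[k] + 1L
        from <- paste0(substr(root_seq, i, i), substr(root_seq, j, j))
        to <- paste0(substr(s, i, i), substr(s, j, j))
        if (from == to) return(tibble())
        tibble(species = tree$tip.label[t], stem = pair_tab$stem[k],
               col5 = pair_tab$pos5[k], col3 = pair_tab$pos3[k],
               from_pair = from, to_pair = to)
      })
    })
    list(
      seqs = leaf_seqs, tree = tree, states = states,
      ancestor = base$seqs %>% mutate(id = "ancestor"),
      truth = c(truth0, list(pair_changes = pair_changes,
                             edge_changes = bind_rows(changes)))
    )
  })
}

#' Calibrated true efficiencies for the reporter fixtures
#'
#' True efficiencies used by the synthetic reporter generator for the two
#' constructs whose efficiencies are quantified in *S. cerevisiae*: 1 percent
#' for the natural `Podo-1` cassette (against the in-frame `Podo0` control)
#' and 0.3 percent for the out-of-frame IBV slippery-site control
#' (`IBV-Podo0`).
#'
#' @return Tibble `construct`, `control`, `true_efficiency_percent`.
#' @export
reporter_calibration <- function() {
  tibble(
    construct = c("Podo-1", "IBV-Podo0"),
    control = c("Podo0", "Podo0"),
    true_efficiency_percent = c(1.0, 0.3)
  )
}

#' Generate synthetic dual-reporter measurements
#'
#' Control luciferase/beta-gal ratios are drawn log-normally around
#' `base_ratio` with coefficient of variation `cv` (mean held exactly at the
#' nominal value), test ratios around `base_ratio * true_efficiency_percent /
#' 100`; beta-gal activities are drawn log-normally around `base_beta_gal`
#' and luciferase activities are reconstructed as `beta_gal * ratio`.
#'
#' @param true_efficiency_percent True frameshifting efficiency (percent).
#' @param n_replicates Replicates per construct (the assay design uses 6).
#' @param cv Multiplicative noise coefficient of variation (0 = noise-free).
#' @param seed RNG seed.
#' @param test,control Construct names.
#' @param base_ratio Control-construct luciferase/beta-gal ratio.
#' @param base_beta_gal Mean beta-galactosidase activity.
#' @return Tibble `construct`, `replicate`, `beta_gal`, `luciferase` with the
#'   generating parameters in `attr(, "truth")`.
#' @examples
#' d <- make_reporter(1, n_replicates = 6, cv = 0, seed = 1)
#' efficiency(d[d$construct == "test", ], d[d$construct == "control", ])
#' @export
make_reporter <- function(true_efficiency_percent = 1, n_replicates = 6L,
                          cv = 0.1, seed = 1L, test = "test",
                          control = "control", base_ratio = 0.6,
                          base_beta_gal = 1000) {
  stopifnot(n_replicates >= 2, cv >= 0, true_efficiency_percent >= 0)
  sigma <- sqrt(log1p(cv^2))
  withr::with_seed(seed, {
    draw <- function(mu, n) {
      mu * exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
    }
    ratios_c <- draw(base_ratio, n_replicates)
    ratios_t <- draw(base_ratio * true_efficiency_percent / 100, n_replicates)
    bg_c <- draw(base_beta_gal, n_replicates)
    bg_t <- draw(base_beta_gal, n_replicates)
    out <- tibble(
      construct = rep(c(test, control), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2),
      beta_gal = c(bg_t, bg_c),
      luciferase = c(bg_t * ratios_t, bg_c * ratios_c)
    )
    attr(out, "truth") <- list(
      true_efficiency_percent = true_efficiency_percent,
      n_replicates = n_replicates, cv = cv, seed = seed
    )
    out
  })
}
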