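test_that("hairpin prediction recovers simple stems and rejects weak ones", {
  b0 <- structure_bounds(min_score = 0)
  hp <- predict_hairpin("GGGGAAAACCCC", b0)
  expect_equal(nrow(hp$pairs), 4)
  expect_equal(hp$pairs$pos5, 0:3)
  expect_equal(hp$pairs$pos3, 11:8)
  expect_equal(hp$score, 12)
  # AT-only stems stay below the default threshold of 12
  expect_null(predict_hairpin("ATATATATAT"))
  expect_null(predict_hairpin(""))
  expect_null(predict_pseudoknot("GGGGAAAACCCC"))  # no crossing stems
})

test_that("the Podo-1 cassette folds into the published pseudoknot", {
  podo <- reporter_inserts()$seq[1]
  site <- scan_slippery(podo)[1, ]
  folds <- fold_downstream(podo, site)
  pk <- folds$pseudoknot
  expect_s3_class(pk, "prf_pseudoknot")
  # stem1 = GGAGGTGGTC paired to GACCAC + CTCC with the GAG bulge
  expect_equal(min(pk$stem1$pairs$pos5), 11)
  expect_equal(nrow(pk$stem1$pairs), 10)
  expect_equal(sum(pk$stem1$bulges$length), 3)
  expect_equal(pk$stem1$bulges$start, 36)   # the bulged GAG block
  feats <- cassette_features(podo, site, pk)
  expect_equal(feats$spacer_nt, 2)
  expect_equal(feats$stem1_bulge_nt, 3)
  expect_gte(feats$stem1_base_gc_run, 2)
  # reported scores are recomputable from the declared scoring function
  expect_equal(score_structure(pk), pk$score)
  expect_equal(score_structure(pk, seq = podo), pk$score)
  # dot-bracket spans the window, brackets match pair counts
  db <- dot_bracket(pk)
  expect_equal(nchar(db), nchar(pk$seq))
  expect_equal(sum(strsplit(db, "")[[1]] == "("), 10)
  expect_equal(sum(strsplit(db, "")[[1]] == "["), nrow(pk$stem2$pairs))
})

test_that("structure upstream of the site is an error", {
  podo <- reporter_inserts()$seq[1]
  site <- scan_slippery(podo)[1, ]
  hp <- predict_hairpin(substr(podo, 1, 20), structure_bounds(min_score = 0))
  expect_error(cassette_features(podo, site, hp), "upstream")
})

test_that("exhaustive search equals the brute-force oracle on small windows", {
  b <- structure_bounds(min_stem = 3, max_stem = 6, max_loop = 12,
                        max_bulges = 2, max_bulge_len = 2,
                        min_hairpin_loop = 3, min_score = -100)
  withr::with_seed(2024, {
    n_pk_found <- 0
    for (k in 1:100) {
      len <- sample(16:34, 1)
      win <- random_dna(len, p_gc = runif(1, 0.3, 0.7))
      hp <- predict_hairpin(win, b)
      expect_equal(if (is.null(hp)) NA_real_ else hp$score,
                   oracle_best_hairpin_score(win, b), info = win)
      pk <- predict_pseudoknot(win, b)
      expect_equal(if (is.null(pk)) NA_real_ else pk$score,
                   oracle_best_pk_score(win, b), info = win)
      if (!is.null(pk)) {
        n_pk_found <- n_pk_found + 1
        expect_true(pk$is_pseudoknot)
        # crossing condition on the returned stems
        expect_lt(max(pk$stem1$pairs$pos5), min(pk$stem2$pairs$pos5))
        expect_lt(max(pk$stem2$pairs$pos5), min(pk$stem1$pairs$pos3))
        expect_lt(max(pk$stem1$pairs$pos3), min(pk$stem2$pairs$pos3))
        # score recomputable
        expect_equal(score_structure(pk, seq = win, bounds = b), pk$score)
        # removing stem2 and rescoring as a hairpin never beats the best
        # hairpin
        s1_loop <- min(pk$stem1$pairs$pos3) - max(pk$stem1$pairs$pos5) - 1
        if (!is.null(hp) && s1_loop >= b$min_hairpin_loop &&
            s1_loop <= b$max_loop) {
          expect_lte(score_structure(pk$stem1, seq = win, bounds = b),
                     hp$score)
        }
      }
    }
    expect_gt(n_pk_found, 5)  # the case mix must actually exercise knots
  })
})

test_that("scores are invariant under RNA spelling and strand mirroring", {
  b <- structure_bounds(min_score = 0, max_stem = 8)
  withr::with_seed(77, {
    for (k in 1:10) {
      win <- random_dna(30, p_gc = 0.6)
      hp <- predict_hairpin(win, b)
      hp_rna <- predict_hairpin(chartr("T", "U", win), b)
      expect_equal(is.null(hp), is.null(hp_rna))
      if (!is.null(hp)) {
        expect_equal(hp_rna$score, hp$score)
        expect_equal(hp_rna$pairs, hp$pairs)
      }
      # strand mirroring preserves Watson-Crick stems (G.U pairs are not
      # symmetric under reverse complement, so compare without them)
      b_wc <- structure_bounds(min_score = 0, max_stem = 8, allow_gu = FALSE)
      hp_wc <- predict_hairpin(win, b_wc)
      hp_rc <- predict_hairpin(reverse_complement(win), b_wc)
      expect_equal(is.null(hp_wc), is.null(hp_rc))
      if (!is.null(hp_wc)) {
        expect_equal(hp_rc$score, hp_wc$score)
        # the mirror of the found optimum scores identically on the mirror
        # strand, so pair counts agree even when ties pick other coordinates
        expect_equal(nrow(hp_rc$pairs), nrow(hp_wc$pairs))
      }
    }
  })
})

test_that("oversized windows are refused with advice", {
  expect_error(predict_pseudoknot(strrep("ACGT", 50)), "smaller window")
})
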