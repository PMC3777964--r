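test_that("pairwise alignment is optimal and passthrough is byte-exact", {
  ident <- align_cassettes(data.frame(id = c("a", "b"),
                                      seq = c("ACGT", "ACGT")))
  expect_equal(ident$seq, c("ACGT", "ACGT"))

  two <- align_cassettes(data.frame(id = c("a", "b"),
                                    seq = c("ACGT", "AGT")))
  expect_equal(sum(strsplit(two$seq[2], "")[[1]] == "-"), 1)
  expect_equal(score_alignment_affine(two$seq[1], two$seq[2]),
               oracle_align_score("ACGT", "AGT"))
  # more exhaustive-oracle cases
  withr::with_seed(12, {
    for (k in 1:8) {
      a <- random_dna(sample(4:7, 1))
      b <- random_dna(sample(3:6, 1))
      al <- align_cassettes(data.frame(id = c("x", "y"), seq = c(a, b)))
      expect_equal(score_alignment_affine(al$seq[1], al$seq[2]),
                   oracle_align_score(a, b), info = paste(a, b))
    }
  })
  pre <- data.frame(id = c("a", "b"), seq = c("AC-GT", "ACCGT"))
  expect_equal(align_cassettes(pre)$seq, pre$seq)
  expect_error(align_cassettes(data.frame(id = character(),
                                          seq = character())), "No sequences")
})

test_that("star-progressive alignment keeps rows consistent", {
  seqs <- data.frame(
    id = c("a", "b", "c", "d"),
    seq = c("ACGTACGTAA", "ACGACGTAA", "ACGTACTTAA", "ACGTACGTA")
  )
  aln <- align_cassettes(seqs)
  expect_equal(length(unique(nchar(aln$seq))), 1)
  expect_equal(gsub("-", "", aln$seq), seqs$seq)
  expect_equal(aln$id, seqs$id)
})

test_that("column pair statistics count the six compatible types", {
  rows6 <- tibble::tibble(
    id = paste0("s", 1:6),
    seq = c("CG", "GC", "AT", "TA", "GT", "TG")
  )
  st <- column_pair_stats(rows6, 0, 1)
  expect_equal(st$n_pair_types, 6)
  expect_equal(st$n_incompatible, 0)

  all_cg <- tibble::tibble(id = paste0("s", 1:4), seq = rep("CG", 4))
  st2 <- column_pair_stats(all_cg, 0, 1)
  expect_equal(st2$n_pair_types, 1)
  expect_equal(st2$n_incompatible, 0)

  mixed <- tibble::tibble(
    id = paste0("s", 1:5),
    seq = c("CG", "CG", "GC", "AA", "A-")
  )
  st3 <- column_pair_stats(mixed, 0, 1)
  expect_equal(st3$n_pair_types, 2)
  expect_equal(st3$n_incompatible, 1)
  expect_equal(st3$n_gapped, 1)

  # permutation invariance across rows
  perm <- mixed[c(3, 5, 1, 4, 2), ]
  expect_equal(column_pair_stats(perm, 0, 1), st3)
  expect_error(column_pair_stats(mixed, 0, 9), "outside")
})

test_that("compensatory calls follow the pairing-preservation rules", {
  # reference pair C-G at columns 0 and 4
  aln <- tibble::tibble(
    id = c("ref", "comp", "wob", "bad", "same"),
    seq = c("CAAAG", "GAAAC", "TAAAG", "AAAAG", "CAAAG")
  )
  stem <- structure(list(
    pairs = tibble::tibble(pos5 = 0L, pos3 = 4L),
    bulges = tibble::tibble(side = character(), start = integer(),
                            length = integer()),
    score = 3, seq = "CAAAG", offset = 0L
  ), class = "prf_stem")
  calls <- find_compensatory(aln, "ref", stem)
  expect_equal(calls$class[calls$species == "comp"], "compensatory")
  expect_equal(calls$class[calls$species == "wob"], "wobble_shift")
  expect_equal(calls$class[calls$species == "bad"], "disruptive")
  expect_false("same" %in% calls$species)
  # identity alignment: zero events
  same <- tibble::tibble(id = c("ref", "x"), seq = c("CAAAG", "CAAAG"))
  expect_equal(nrow(find_compensatory(same, "ref", stem)), 0)
})

test_that("compensatory recall is total on families with pairing preserved", {
  withr::with_seed(31, {
    tree <- ape::rtree(8)
    tree$tip.label <- paste0("sp", 1:8)
  })
  fam <- make_family(tree, cassette_spec(seed = 51), rate = 0.06,
                     compensatory_fraction = 1, seed = 8)
  aln <- as_cassette_alignment(dplyr::bind_rows(fam$ancestor, fam$seqs))
  anc <- fam$ancestor$seq
  site <- scan_slippery(anc)
  site <- site[site$start == fam$truth$heptamer_start, ]
  pk <- fold_downstream(anc, site)$pseudoknot
  calls <- find_compensatory(aln, "ancestor", pk)
  truth <- fam$truth$pair_changes
  expect_gt(nrow(truth), 0)
  joined <- dplyr::inner_join(calls, truth, by = c("species", "col5", "col3"))
  expect_equal(nrow(joined), nrow(truth))           # recall 1.0
  expect_false(any(calls$class == "disruptive"))    # pairing preserved
})

test_that("extension frames classify as -1, +1 or in-frame", {
  o5 <- tibble::tibble(frame = 0L)
  expect_equal(classify_extension_frame(o5, tibble::tibble(frame = 2L)), "-1")
  expect_equal(classify_extension_frame(o5, tibble::tibble(frame = 1L)), "+1")
  expect_equal(classify_extension_frame(o5, tibble::tibble(frame = 0L)),
               "in_frame")
})

test_that("parsimony on the packaged tree gives one gain and one loss", {
  yd <- yip3_character_data()
  fit <- fitch_map(yd$tree, yd$states)
  g <- glance(fit)
  expect_equal(g$n_changes, 2)
  expect_equal(g$n_gains, 1)
  expect_equal(g$n_losses, 1)
  events <- tidy(fit)
  expect_equal(events$child_label[events$event == "loss"], "Ascosphaera_apis")
  # the gain sits on the edge to the Pezizomycotina clade that excludes the
  # Orbiliomycetes
  gain_child <- events$child[events$event == "gain"]
  core <- ape::getMRCA(yd$tree, c("Tuber_melanosporum",
                                  "Podospora_anserina"))
  expect_equal(gain_child, core)
  # exhaustive check of the minimum change count on the packaged tree
  expect_equal(oracle_fitch_count(yd$tree, yd$states), 2)
})

test_that("parsimony handles stars, agrees with brute force and phangorn", {
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  all_p <- tibble::tibble(species = letters[1:5], state = "present")
  fit <- fitch_map(star, all_p)
  expect_equal(fit$n_changes, 0)
  expect_equal(nrow(tidy(fit)), 0)

  withr::with_seed(19, {
    for (k in 1:25) {
      tr <- ape::rtree(8)
      tr$tip.label <- letters[1:8]
      st <- tibble::tibble(species = letters[1:8],
                           state = sample(c("present", "absent"), 8,
                                          replace = TRUE))
      fit <- fitch_map(tr, st)
      expect_equal(fit$n_changes, oracle_fitch_count(tr, st))
      expect_equal(nrow(tidy(fit)), fit$n_changes)
      m <- matrix(st$state, ncol = 1, dimnames = list(st$species, NULL))
      pd <- phangorn::phyDat(m, type = "USER",
                             levels = c("absent", "present"))
      expect_equal(fit$n_changes, as.integer(phangorn::fitch(tr, pd)))
    }
  })
  expect_error(fitch_map(star, all_p[1:3, ]), "d, e")
})
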