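test_that("re-pairing classes follow the antiparallel wobble rules", {
  # Ser (IGA) re-pairing on the -1 codon UUC: A.U Watson-Crick, G.U wobble,
  # I.C inosine (codon 5'->3')
  expect_equal(repair_pairs("TCC", "TTC"), c("WC", "wobble", "inosine"))
  # RNA spelling is equivalent
  expect_equal(repair_pairs("UCC", "UUC"), c("WC", "wobble", "inosine"))
  # identity re-pairing equals cognate decoding: no mismatch anywhere
  expect_true(all(repair_pairs("TTT", "TTT") != "mismatch"))
  # complement codon: at least two mismatches
  expect_gte(sum(repair_pairs("TCC", "AGG") == "mismatch"), 2)
  expect_error(repair_pairs("TAA", "TTC"), "sense")
  expect_error(repair_pairs("TTC", "TGA"), "stop")
})

test_that("scanning finds the PaYIP3 and IBV sites and nothing in GC repeats", {
  ins <- reporter_inserts()
  podo <- ins$seq[ins$id == "Podo-1"]
  s <- scan_slippery(podo, mode = "relaxed", shift = -1)
  hit <- s[s$start == 2, ]
  expect_equal(hit$heptamer, "TTTTTCC")
  expect_equal(hit$model, "tandem")
  expect_equal(hit$a_classes[[1]], c("WC", "wobble", "inosine"))

  sp6 <- ins$seq[ins$id == "IBV-Podo-1_sp6"]
  can <- scan_slippery(sp6, mode = "canonical", shift = -1)
  expect_true(any(can$start == 2 & can$heptamer == "TTTAAAC"))

  expect_equal(nrow(scan_slippery("GCGCGCGCGC", "relaxed")), 0)
  expect_equal(nrow(scan_slippery("GCGCGCGCGC", "canonical")), 0)

  # DNA/RNA spelling invariance
  s_rna <- scan_slippery(chartr("T", "U", podo))
  expect_equal(s_rna$start, s$start)
  expect_equal(s_rna$heptamer, s$heptamer)
})

test_that("every canonical X XXY YYZ heptamer is accepted in relaxed mode", {
  bases <- c("A", "C", "G", "T")
  all_hept <- do.call(paste0, expand.grid(rep(list(bases), 7),
                                          stringsAsFactors = FALSE))
  tab <- anticodon_table()
  memo <- new.env(parent = emptyenv())
  accept <- function(h) {
    p0 <- substr(h, 2, 4)
    a0 <- substr(h, 5, 7)
    ps <- substr(h, 1, 3)
    as <- substr(h, 4, 6)
    key <- h
    ok <- function(from, to) {
      k <- paste0(from, to)
      v <- memo[[k]]
      if (is.null(v)) {
        v <- if (from %in% tab$codon && !to %in% c("TAA", "TAG", "TGA")) {
          oracle_repairs_ok(from, to, tab)
        } else FALSE
        memo[[k]] <- v
      }
      v
    }
    ok(p0, ps) && ok(a0, as)
  }
  canonical <- substr(all_hept, 1, 1) == substr(all_hept, 2, 2) &
    substr(all_hept, 2, 2) == substr(all_hept, 3, 3) &
    substr(all_hept, 4, 4) == substr(all_hept, 5, 5) &
    substr(all_hept, 5, 5) == substr(all_hept, 6, 6)
  accepted <- vapply(all_hept, accept, logical(1))
  expect_true(all(accepted[canonical]))
  # and the oracle agrees with classify_site on a random subset
  withr::with_seed(5, idx <- sample(length(all_hept), 200))
  for (h in all_hept[idx]) {
    site <- slippery_site(h, 0, shift = -1)
    expect_equal(classify_site(site) == "tandem", unname(accepted[h]),
                 info = h)
  }
})

test_that("slippage models separate tandem, single-P and incompatible sites", {
  # PaYIP3: full tandem re-pairing
  expect_equal(classify_site(slippery_site("TTTTTCC", 0, -1)), "tandem")
  # IBV reference site is tandem
  expect_equal(classify_site(slippery_site("TTTAAAC", 0, -1)), "tandem")
  # UUUCU-centred +1 site: the P-site tRNA (Phe GAA) re-pairs on UUC, but
  # the A-site tRNA (Leu CAG, decoding CUG) cannot re-pair on UGC
  site <- slippery_site("ATTTTCTGC", 1, shift = +1)
  expect_equal(site$heptamer, "TTTTCTG")
  expect_equal(site$a_codon_shift, "TGC")
  expect_equal(classify_site(site), "single_P")
  # a site that fails already at the P-site tRNA
  bad <- slippery_site("GCGCGCGC", 0, -1)
  expect_equal(classify_site(bad), "incompatible")
})

test_that("+1 scanning uses one base of context past the heptamer", {
  # the last scannable +1 heptamer leaves room for offset 7
  s <- scan_slippery("AAAAAAAAA", mode = "relaxed", shift = +1)
  expect_true(all(s$start <= 1))
  expect_error(slippery_site("AAAAAAA", 0, shift = +1), "outside")
})
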