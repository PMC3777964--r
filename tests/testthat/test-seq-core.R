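test_that("FASTA reading normalises RNA, keeps order, rejects bad input", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">x", "GCUU"), f)
  d <- read_fasta(f)
  expect_equal(d$seq, "GCTT")
  expect_true(d$is_rna)

  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "Duplicate")

  writeLines(c(">a", "ACXT"), f)
  expect_error(read_fasta(f), "X")

  writeLines(character(0), f)
  expect_equal(nrow(suppressWarnings(read_fasta(f))), 0)

  expect_error(read_fasta(tempfile()), "not found")
})

test_that("FASTA write/read round-trips content regardless of wrapping", {
  withr::with_seed(42, {
    seqs <- tibble::tibble(
      id = paste0("s", 1:5),
      seq = vapply(sample(40:200, 5), random_dna, character(1))
    )
  })
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f, width = 17)
  back <- read_fasta(f)
  expect_equal(back$id, seqs$id)
  expect_equal(back$seq, seqs$seq)
})

test_that("packaged reporter inserts match their printed lengths and file copy", {
  ins <- reporter_inserts()
  expect_equal(nchar(ins$seq), c(59, 60, 62, 59, 65))
  # the in-frame control is the -1 insert with one extra 5' G
  expect_equal(ins$seq[ins$id == "Podo0"],
               paste0("G", ins$seq[ins$id == "Podo-1"]))
  # drift guard: the shipped FASTA and the package constants agree
  f <- system.file("extdata", "reporter_inserts.fasta", package = "prfscan")
  disk <- read_fasta(f)
  expect_equal(disk$id, ins$id)
  expect_equal(disk$seq, ins$seq)
})

test_that("translation follows the standard code and stop policies", {
  expect_equal(translate_cds("ATG"), "M")
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_equal(translate_cds("ATGAAATAA", stop_policy = "read_through"),
               "MK*")
  podo <- reporter_inserts()$seq[1]
  rt <- translate_cds(podo, 0, "read_through")
  # translation in the zero frame terminates at codon index 7 (0-based)
  expect_equal(substr(rt, 8, 8), "*")
  expect_equal(nchar(translate_cds(podo, 0)), 7)
  # the -1-shifted register of the insert has no stop anywhere
  expect_false(grepl("*", translate_cds(podo, 1, "read_through"),
                     fixed = TRUE))
  # trailing partial codon dropped
  expect_equal(translate_cds("ATGAA"), "M")
  expect_error(translate_cds("ATG", start = 7), "outside")
})

test_that("find_orfs matches examples and a brute-force scanner", {
  one <- find_orfs("ATGAAATAA", min_aa = 2, require_atg = TRUE)
  expect_equal(nrow(one), 1)
  expect_equal(one$aa_seq, "MK")
  expect_equal(c(one$start, one$end, one$frame), c(0, 9, 0))
  expect_true(one$has_terminal_stop)

  expect_equal(nrow(find_orfs(strrep("A", 60), min_aa = 2,
                              require_atg = TRUE)), 0)

  withr::with_seed(7, {
    for (k in 1:30) {
      seq <- random_dna(sample(30:300, 1))
      min_aa <- sample(1:5, 1)
      atg <- sample(c(TRUE, FALSE), 1)
      got <- as.data.frame(find_orfs(seq, min_aa, atg))
      want <- oracle_orfs(seq, min_aa, atg)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  })
})

test_that("ORF coordinate invariant holds: length, frame, terminal stop", {
  withr::with_seed(11, {
    for (k in 1:10) {
      seq <- random_dna(150)
      orfs <- find_orfs(seq, min_aa = 2)
      if (nrow(orfs) == 0) next
      expect_true(all((orfs$end - orfs$start) %% 3 == 0))
      expect_true(all(orfs$start %% 3 == orfs$frame))
      expect_equal(nchar(orfs$aa_seq),
                   (orfs$end - orfs$start) / 3 - orfs$has_terminal_stop)
    }
  })
})

test_that("protein masses are the residue sums plus water, and additive", {
  expect_equal(protein_mass(""), 18.02, tolerance = 1e-3)
  expect_equal(protein_mass("GG"), 132.12, tolerance = 1e-4)
  expect_error(protein_mass("GXG"), "X")
  withr::with_seed(3, {
    aas <- c("MKWVTFISLLFLFSSAYS", "ACDEFGHIKLMNPQRSTVWY", "PPP")
    for (a in aas) {
      for (b in aas) {
        expect_equal(protein_mass(paste0(a, b)),
                     protein_mass(a) + protein_mass(b) - protein_mass(""),
                     tolerance = 1e-9)
      }
    }
  })
  # monoisotopic masses are smaller than average ones
  expect_lt(protein_mass("W", "monoisotopic"), protein_mass("W"))
})
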