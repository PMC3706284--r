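toy_msa <- function() {
  Biostrings::DNAStringSet(c(
    Homo_sapiens = "AC-GT",
    sp2          = "ACCGT",
    sp3          = "ATCGA",
    sp4          = "-CCGT"))
}

test_that("position-column mapping skips reference gaps", {
  msa <- toy_msa()
  map <- mapMsaColumns(msa, "Homo_sapiens", coordinate_offset = 100L)
  expect_equal(map$position, c(101L, 102L, 103L, 104L))
  expect_equal(map$column, c(1L, 2L, 4L, 5L))   # column 3 is a reference gap
  gapless <- Biostrings::DNAStringSet(c(Homo_sapiens = "ACGT"))
  m2 <- mapMsaColumns(gapless)
  expect_equal(m2$position, m2$column)
  expect_error(mapMsaColumns(msa, "nonexistent"), "not found")
})

test_that("conservation index counts matching rows, gaps as mismatches", {
  msa <- toy_msa()
  # position 101 -> column 1: A,A,A,- => 3/4
  ci <- conservationIndex(msa, 101L, coordinate_offset = 100L)
  expect_equal(ci$matches, 3L)
  expect_equal(ci$total_species, 4L)
  expect_equal(ci$ci_percent, 75.0)
  expect_equal(ci$bin, "mid")
  expect_error(conservationIndex(msa, 999L, coordinate_offset = 100L),
               "not mapped")
})

test_that("printed-style CI values and bins are reproduced", {
  human <- strrep("A", 30)
  profile <- rep(22L, 30)
  profile[1:4] <- c(22L, 18L, 11L, 17L)
  msa <- generateMsa(human, profile, seed = 5L)
  ci <- conservationIndex(msa, 1:4)
  expect_equal(ci$ci_percent, c(100.0, 81.8, 50.0, 77.3))
  expect_equal(ci$bin, c("high", "high", "mid", "mid"))
})

test_that("conservation index is invariant under row permutation", {
  set.seed(12)
  human <- randomDna(40)
  profile <- sample(1:22, 40, replace = TRUE)
  msa <- generateMsa(human, profile, seed = 6L)
  ci0 <- conservationIndex(msa, seq_len(40),
                           wildtype_base = strsplit(human, "")[[1]])
  for (rep in 1:5) {
    perm <- sample(length(msa))
    ci1 <- conservationIndex(msa[perm], seq_len(40),
                             wildtype_base = strsplit(human, "")[[1]],
                             reference_row_id = match(1L, perm))
    expect_equal(ci1$matches, ci0$matches)
    expect_equal(ci1$ci_percent, ci0$ci_percent)
    expect_equal(ci1$bin, ci0$bin)
  }
})

test_that("bin counting partitions the records", {
  recs <- data.frame(bin = c("high", "high", "mid", "low"))
  expect_equal(summarizeCiBins(recs),
               c(n_high = 2L, n_mid = 1L, n_low = 1L))
  expect_equal(summarizeCiBins(recs[0, , drop = FALSE]),
               c(n_high = 0L, n_mid = 0L, n_low = 0L))
  all_high <- data.frame(bin = rep("high", 7))
  expect_equal(unname(summarizeCiBins(all_high)), c(7L, 0L, 0L))
})

test_that("triage rules fire in priority order", {
  cat0 <- testCatalogue()
  expect_equal(triageMtVariant("m.1222A>G", 1, 0, 100.0, cat0)$tclass,
               "putative_deafness_associated")
  expect_equal(triageMtVariant("m.709G>A", 143, 109, 63.6, cat0)$tclass,
               "polymorphism")
  expect_equal(triageMtVariant("m.979C>T", 1, 0, 27.3, cat0)$tclass,
               "unclassified")
  # literature label beats the control-presence rule
  r1095 <- triageMtVariant("m.1095T>C", 6, 1, 100.0, cat0)
  expect_equal(r1095$tclass, "known_pathogenic")
  expect_equal(r1095$rule_fired, "known_pathogenic_set")
  # ... and beats the putative rule at position 961
  expect_equal(triageMtVariant("m.961delT+insC", 2, 0, 90.9, cat0)$tclass,
               "known_pathogenic")
  # high conservation does not rescue a variant present in controls
  expect_equal(triageMtVariant("m.1598G>A", 14, 10, 100.0, cat0)$tclass,
               "polymorphism")
})
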