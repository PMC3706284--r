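test_that("pure-tone average is the arithmetic mean of four thresholds", {
  expect_equal(ptaAverage(c(40, 40, 40, 40)), 40)
  expect_equal(ptaAverage(c(30, 40, 50, 60)), 45)
  expect_equal(ptaAverage(c(20, 30, 90, 100)), 60)
  expect_error(ptaAverage(c(40, 40, 40)), "four thresholds")
  expect_error(ptaAverage(c(40, 40, 40, NA)), "four thresholds")
  m <- data.frame(a = c(40, 30), b = c(40, 40), c = c(40, 50), d = c(40, 60))
  expect_equal(ptaAverage(m), c(40, 45))
})

test_that("severity banding follows the audiometric rule", {
  expect_equal(classifySeverity(35), "mild")
  expect_equal(classifySeverity(26), "mild")
  expect_equal(classifySeverity(40), "mild")
  expect_equal(classifySeverity(40.5), "moderate")  # real-line banding
  expect_equal(classifySeverity(60), "moderate")
  expect_equal(classifySeverity(80), "severe")
  expect_equal(classifySeverity(81), "profound")
  expect_equal(classifySeverity(10), "normal")
  expect_equal(classifySeverity(c(25.9, 26)), c("normal", "mild"))
})

test_that("genotype classes follow the pathogenic-allele count", {
  cat0 <- testCatalogue()
  expect_equal(assignGenotype("c.235delC", "c.235delC", cat0)$gclass,
               "biallelic_homozygous")
  expect_equal(assignGenotype("c.257C>G", "c.605ins46", cat0)$gclass,
               "biallelic_compound_het")
  expect_equal(assignGenotype("c.235delC", character(), cat0)$gclass,
               "monoallelic")
  expect_equal(assignGenotype("c.79G>A", "-", cat0)$gclass,
               "polymorphism_or_unknown_only")
  expect_equal(assignGenotype("c.368C>A", "c.571T>C", cat0)$gclass,
               "polymorphism_or_unknown_only")  # unknowns never count
  expect_equal(assignGenotype(character(), character(), cat0)$gclass, "none")
  # a pathogenic plus a polymorphism in trans is still monoallelic
  expect_equal(assignGenotype("c.235delC", "c.79G>A", cat0)$gclass,
               "monoallelic")
})

test_that("cross-tabulation partitions the case cohort", {
  cat0 <- testCatalogue()
  subj <- data.frame(
    subject_id = c("a", "b", "c", "d"),
    group = c("case", "case", "case", "control"),
    thr_500 = c(50, 70, 90, 10), thr_1000 = c(50, 70, 90, 10),
    thr_2000 = c(50, 70, 90, 10), thr_4000 = c(50, 70, 90, 10),
    onset = c("prelingual", "prelingual", "postlingual", "unknown"),
    stringsAsFactors = FALSE)
  gen <- rbind(assignGenotype("c.235delC", "c.235delC", cat0, "a"),
               assignGenotype("c.235delC", "c.235delC", cat0, "b"),
               assignGenotype(character(), character(), cat0, "c"),
               assignGenotype(character(), character(), cat0, "d"))
  x <- crosstabGenotypePhenotype(gen, subj)
  expect_equal(sum(x$n), 3L)  # control excluded
  hom <- x[x$allele1 == "c.235delC", ]
  expect_equal(hom$n, 2L)
  expect_equal(hom$moderate, 1L)
  expect_equal(hom$severe, 1L)
  expect_equal(hom$onset_pre, 2L)
  none <- x[x$allele1 == "-", ]
  expect_equal(none$profound, 1L)
  expect_equal(none$onset_post, 1L)
  # empty cohort -> empty table
  empty <- crosstabGenotypePhenotype(gen, subj[subj$group == "none", ])
  expect_equal(nrow(empty), 0L)
})

test_that("more than two nuclear allele sequences is an input error", {
  cat0 <- testCatalogue()
  refs <- referenceSetOf(cat0)
  gref <- as.character(gjb2Cds(refs))
  recs <- data.frame(
    id = paste0("S1|GJB2|", 1:3), subject_id = "S1", locus = "GJB2",
    allele_index = c("1", "2", "3"), sequence = gref,
    stringsAsFactors = FALSE)
  subj <- data.frame(subject_id = "S1", group = "case",
                     stringsAsFactors = FALSE)
  expect_error(screenCohort(recs, subj, refs, cat0), "more than two")
})
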