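small_spec <- function(cat0, seed = 3L) {
  gt <- data.frame(
    allele1 = c("c.235delC", "c.235delC", "c.79G>A"),
    allele2 = c("c.299delAT", "c.235delC", "-"),
    stratum = c("pathogenic_biallelic", "pathogenic_biallelic",
                "polymorphism_unknown"),
    case_count = c(2L, 3L, 4L), control_count = c(0L, 0L, 2L),
    stringsAsFactors = FALSE)
  mt <- data.frame(name = c("m.1555A>G", "m.750A>G"),
                   case_count = c(3L, 10L), control_count = c(0L, 5L),
                   stringsAsFactors = FALSE)
  cohortSpec(12L, 8L, gt, mt, seed = seed)
}

test_that("impossible stratum counts are rejected", {
  cat0 <- testCatalogue()
  gt <- data.frame(allele1 = "c.235delC", allele2 = "-",
                   stratum = "pathogenic_monoallelic",
                   case_count = 5L, control_count = 0L)
  mt <- data.frame(name = "m.1555A>G", case_count = 0L, control_count = 0L)
  expect_error(cohortSpec(3L, 2L, gt, mt), "exceed")
  expect_error(cohortSpec(10L, 2L, gt,
                          data.frame(name = "m.1555A>G", case_count = 11L,
                                     control_count = 0L)),
               "exceed")
})

test_that("planted genotypes differ from the reference exactly at the planted sites", {
  cat0 <- testCatalogue()
  refs <- referenceSetOf(cat0)
  gt <- data.frame(allele1 = "c.235delC", allele2 = "c.299delAT",
                   stratum = "pathogenic_biallelic",
                   case_count = 1L, control_count = 0L)
  mt <- data.frame(name = character(), case_count = integer(),
                   control_count = integer())
  coh <- generateCohort(cohortSpec(1L, 0L, gt, mt, seed = 1L), refs, cat0)
  gref <- as.character(gjb2Cds(refs))
  a1 <- coh$records$sequence[coh$records$locus == "GJB2" &
                               coh$records$allele_index == "1"]
  a2 <- coh$records$sequence[coh$records$locus == "GJB2" &
                               coh$records$allele_index == "2"]
  # allele 1: single-base deletion at c.235; allele 2: two-base deletion at 299
  expect_equal(a1, paste0(substr(gref, 1, 234), substr(gref, 236, nchar(gref))))
  expect_equal(a2, paste0(substr(gref, 1, 298), substr(gref, 301, nchar(gref))))
})

test_that("an all-zero specification yields a wild-type cohort", {
  cat0 <- testCatalogue()
  refs <- referenceSetOf(cat0)
  gt <- data.frame(allele1 = "c.235delC", allele2 = "-",
                   stratum = "pathogenic_monoallelic",
                   case_count = 0L, control_count = 0L)
  mt <- data.frame(name = "m.1555A>G", case_count = 0L, control_count = 0L)
  coh <- generateCohort(cohortSpec(3L, 2L, gt, mt, seed = 2L), refs, cat0)
  gref <- as.character(gjb2Cds(refs))
  mref <- as.character(mt12sSeq(refs))
  expect_true(all(coh$records$sequence[coh$records$locus == "GJB2"] == gref))
  expect_true(all(coh$records$sequence[coh$records$locus == "MT12S"] == mref))
  expect_equal(nrow(coh$truth$mt_carriers), 0L)
})

test_that("generation is deterministic under the seed", {
  cat0 <- testCatalogue()
  refs <- referenceSetOf(cat0)
  a <- generateCohort(small_spec(cat0, seed = 9L), refs, cat0)
  b <- generateCohort(small_spec(cat0, seed = 9L), refs, cat0)
  d <- generateCohort(small_spec(cat0, seed = 10L), refs, cat0)
  expect_identical(a$records, b$records)
  expect_identical(a$subjects, b$subjects)
  expect_false(identical(a$subjects, d$subjects))
})

test_that("the screen recovers the generator's planted counts", {
  cat0 <- testCatalogue()
  refs <- referenceSetOf(cat0)
  spec <- small_spec(cat0)
  coh <- generateCohort(spec, refs, cat0)
  scr <- screenCohort(coh$records, coh$subjects, refs, cat0)
  res <- summarizeScreen(scr, coh$subjects, cat0)
  g <- res$gjb2_table
  expect_equal(g$case_carriers[g$name == "c.235delC"], 5L)   # 2 + 3 subjects
  expect_equal(g$case_carriers[g$name == "c.299delAT"], 2L)
  expect_equal(g$case_carriers[g$name == "c.79G>A"], 4L)
  expect_equal(g$control_carriers[g$name == "c.79G>A"], 2L)
  m <- res$mt_table
  expect_equal(m$case_carriers[m$name == "m.1555A>G"], 3L)
  expect_equal(m$case_carriers[m$name == "m.750A>G"], 10L)
  expect_equal(m$control_carriers[m$name == "m.750A>G"], 5L)
  expect_equal(res$gjb2_summary$n_homozygous, 3L)
  expect_equal(res$gjb2_summary$n_compound_het, 2L)
})

test_that("aminoglycoside mitochondrial mutations avoid pathogenic GJB2 carriers", {
  cat0 <- testCatalogue()
  refs <- referenceSetOf(cat0)
  coh <- generateCohort(small_spec(cat0, seed = 21L), refs, cat0)
  g <- coh$truth$genotypes
  path_ids <- g$subject_id[g$stratum %in% c("pathogenic_monoallelic",
                                            "pathogenic_biallelic")]
  mt1555 <- coh$truth$mt_carriers$subject_id[
    coh$truth$mt_carriers$name == "m.1555A>G"]
  expect_length(intersect(path_ids, mt1555), 0L)
})

test_that("generated alignments meet the conservation profile exactly", {
  human <- "ACGTACGTACGTACGTACGT"
  profile <- rep(22L, 20L)
  profile[5] <- 20L
  profile[10] <- 1L
  msa <- generateMsa(human, profile, n_species = 22L, seed = 4L)
  expect_length(msa, 22L)
  chmat <- do.call(rbind, strsplit(as.character(msa), ""))
  hb <- strsplit(human, "")[[1]]
  counts <- vapply(seq_len(20L), function(j) sum(chmat[, j] == hb[j]),
                   integer(1))
  expect_equal(counts, profile)
  ci <- conservationIndex(msa, c(5L, 10L, 1L))
  expect_equal(ci$ci_percent, c(90.9, 4.5, 100.0))
  # deterministic under seed
  expect_identical(as.character(generateMsa(human, profile, seed = 4L)),
                   as.character(msa))
  expect_error(generateMsa(human, rep(0L, 20L)), "\\[1, n_species\\]")
})
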