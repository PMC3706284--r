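test_that("planted catalogue variants round-trip to their printed names", {
  cat0 <- testCatalogue()
  defs <- variantDefinitions(cat0)
  refs <- referenceSetOf(cat0)
  expect_equal(nrow(defs), 45L)
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    lr <- deafscreen:::.locus_ref(refs, d$locus)
    mut <- plantVariant(lr$seq, d, coordinate_offset = lr$offset)
    got <- callVariants(mut, refs, d$locus)
    expect_equal(nrow(got), 1L, info = d$name)
    expect_equal(got$name, d$name, info = d$name)
  }
})

test_that("event extraction classifies runs of altered columns", {
  cat0 <- testCatalogue()
  refs <- referenceSetOf(cat0)
  defs <- variantDefinitions(cat0)
  gref <- as.character(gjb2Cds(refs))

  mnv <- callVariants(plantVariant(gref, defs[defs$name == "c.608TC>AA", ]),
                      refs, "GJB2")
  expect_equal(mnv$kind, "mnv_substitution")
  expect_equal(mnv$position, 608L)
  expect_equal(mnv$ref_allele, "TC")
  expect_equal(mnv$alt_allele, "AA")

  del <- callVariants(plantVariant(gref, defs[defs$name == "c.176del16", ]),
                      refs, "GJB2")
  expect_equal(del$kind, "deletion")
  expect_equal(del$position, 176L)
  expect_equal(nchar(del$ref_allele), 16L)

  expect_equal(nrow(callVariants(gref, refs, "GJB2")), 0L)
})

test_that("indels left-normalize to their left-most equivalent placement", {
  # deletion of the third C in ACCCG is the same edit as deleting the first
  ref <- "ACCCG"
  call <- variantCall("GJB2", "deletion", 4, "C", "")
  norm <- normalizeVariant(call, ref)
  expect_equal(norm$position, 2L)
  # re-applying the normalized edit reproduces the original edited string
  orig <- paste0(substr(ref, 1, 3), substr(ref, 5, 5))
  expect_equal(plantVariant(ref, norm), orig)
  # idempotent
  expect_identical(normalizeVariant(norm, ref), norm)
  # substitutions are untouched
  sub <- variantCall("GJB2", "substitution", 3, "C", "T")
  expect_identical(normalizeVariant(sub, ref), sub)
  # insertion into a homopolymer goes left-most
  ins <- variantCall("GJB2", "insertion", 5, "", "C")  # ACCCG, ins C before G
  expect_equal(normalizeVariant(ins, "ACCCG")$position, 2L)
})

test_that("left-shift preserves the edit on random homopolymer contexts", {
  set.seed(5)
  for (rep in 1:50) {
    ref <- paste0(randomDna(4), strrep(sample(c("A", "C", "G", "T"), 1),
                                       sample(2:5, 1)), randomDna(4))
    p <- sample(5:(nchar(ref) - 4), 1)
    call <- variantCall("GJB2", "deletion", p, substr(ref, p, p), "")
    norm <- normalizeVariant(call, ref)
    expect_lte(norm$position, call$position)
    expect_equal(plantVariant(ref, norm), plantVariant(ref, call))
  }
})

test_that("the naming policy reproduces each printed spelling", {
  expect_equal(nameVariant(variantCall("GJB2", "deletion", 235, "C", "")),
               "c.235delC")
  expect_equal(nameVariant(variantCall("GJB2", "deletion", 299, "AT", "")),
               "c.299delAT")
  expect_equal(nameVariant(variantCall("GJB2", "deletion", 176,
                                       strrep("A", 16), "")),
               "c.176del16")
  expect_equal(nameVariant(variantCall("GJB2", "insertion", 504, "", "AAGG")),
               "c.504insAAGG")
  expect_equal(nameVariant(variantCall("GJB2", "insertion", 605, "",
                                       randomDna(46))),
               "c.605ins46")
  expect_equal(nameVariant(variantCall("MT12S", "substitution", 1555,
                                       "A", "G")),
               "m.1555A>G")
  expect_equal(nameVariant(variantCall("MT12S", "delins", 961, "T", "CC")),
               "m.961delT+insC")
})

test_that("ambiguous bases at a variant site are excluded with a warning", {
  cat0 <- testCatalogue()
  refs <- referenceSetOf(cat0)
  gref <- as.character(gjb2Cds(refs))
  mut <- paste0(substr(gref, 1, 234), "N", substr(gref, 236, nchar(gref)))
  expect_warning(got <- callVariants(mut, refs, "GJB2"), "ambiguous")
  expect_equal(nrow(got), 0L)
})

test_that("planting checks the reference allele", {
  expect_error(
    plantVariant("ACGT", variantCall("GJB2", "substitution", 2, "G", "T")),
    "mismatch")
  expect_error(
    plantVariant("ACGT", variantCall("GJB2", "substitution", 9, "A", "T")),
    "outside")
  expect_equal(plantVariants("ACGT", deafscreen:::.empty_calls()), "ACGT")
})
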