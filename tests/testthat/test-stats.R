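test_that("carrier frequencies are half-up percentages", {
  expect_equal(carrierFrequency(102, 658), 15.50)
  expect_equal(carrierFrequency(0, 462), 0.00)
  expect_equal(carrierFrequency(39, 658), 5.93)   # 5.9270 rounds up
  expect_equal(carrierFrequency(70, 658), 10.64)
  expect_error(carrierFrequency(1, 0), "positive")
  expect_error(carrierFrequency(5, 4), "\\[0, n\\]")
  # half-up, not banker's
  expect_equal(roundHalfUp(0.125, 2), 0.13)
  expect_equal(roundHalfUp(-0.125, 2), -0.13)
  expect_equal(roundHalfUp(77.2727, 1), 77.3)
})

make_carriers <- function() {
  data.frame(
    subject_id = c("a", "a", "b", "b", "c", "x"),
    group = c("case", "case", "case", "case", "case", "control"),
    name = c("v1", "v1", "v1", "v2", "v2", "v1"),
    stringsAsFactors = FALSE)
}

test_that("a subject counts once per variant regardless of allele count", {
  tab <- tallyCarriers(make_carriers(), n_cases = 10L, n_controls = 5L)
  expect_equal(tab$case_carriers[tab$name == "v1"], 2L)  # duplicate a row
  expect_equal(tab$case_carriers[tab$name == "v2"], 2L)
  expect_equal(tab$control_carriers[tab$name == "v1"], 1L)
  expect_equal(tab$case_freq[tab$name == "v1"], 20.00)
})

test_that("adding a carrier never decreases a frequency", {
  base <- make_carriers()
  tab0 <- tallyCarriers(base, 40L, 5L)
  set.seed(8)
  for (rep in 1:20) {
    extra <- data.frame(subject_id = paste0("n", rep), group = "case",
                        name = sample(c("v1", "v2"), 1),
                        stringsAsFactors = FALSE)
    tab1 <- tallyCarriers(rbind(base, extra), 40L, 5L)
    expect_true(all(tab1$case_freq >= tab0$case_freq))
    base <- rbind(base, extra)
    tab0 <- tab1
  }
})

test_that("variant aggregation sums carriers and can exceed the union", {
  carriers <- data.frame(
    subject_id = c("a", "a", "b"), group = "case",
    name = c("v1", "v2", "v1"), stringsAsFactors = FALSE)
  tab <- tallyCarriers(carriers, 10L, 5L)
  agg <- aggregateVariants(tab, c("v1", "v2"))
  expect_equal(agg$count, 3L)                      # a counted twice
  expect_equal(length(unique(carriers$subject_id)), 2L)
  expect_equal(agg$freq, 30.00)
  single <- aggregateVariants(tab, "v2")
  expect_equal(single$count, 1L)
  expect_error(aggregateVariants(tab, "v99"), "not present")
})

test_that("genotype summary fields satisfy their identities", {
  cat0 <- testCatalogue()
  gen <- rbind(assignGenotype("c.235delC", "c.235delC", cat0, "a"),
               assignGenotype("c.257C>G", "c.605ins46", cat0, "b"),
               assignGenotype("c.235delC", character(), cat0, "c"),
               assignGenotype("c.79G>A", "-", cat0, "d"),
               assignGenotype(character(), character(), cat0, "e"))
  gen$group <- "case"
  s <- summarizeGjb2(gen, n_cases = 5L)
  expect_equal(s$n_biallelic, s$n_homozygous + s$n_compound_het)
  expect_equal(s$n_pathogenic_carriers, s$n_biallelic + s$n_monoallelic)
  expect_equal(s$n_pathogenic_carriers, 3L)
  expect_equal(s$pathogenic_carrier_freq, 60.00)
  empty <- summarizeGjb2(gen[0, ], n_cases = 5L)
  expect_equal(empty$n_pathogenic_carriers, 0L)
  expect_equal(empty$pathogenic_carrier_freq, 0.00)
})

test_that("the combined rate uses union semantics over subjects", {
  cat0 <- testCatalogue()
  gen <- rbind(assignGenotype("c.235delC", "c.235delC", cat0, "a"),
               assignGenotype(character(), character(), cat0, "b"),
               assignGenotype(character(), character(), cat0, "c"))
  gen$group <- "case"
  mt_disjoint <- data.frame(subject_id = "b", group = "case",
                            name = "m.1555A>G", stringsAsFactors = FALSE)
  mt_overlap <- data.frame(subject_id = "a", group = "case",
                           name = "m.1555A>G", stringsAsFactors = FALSE)
  expect_equal(combinedDeafnessFrequency(gen, mt_disjoint, n_cases = 4L),
               50.00)   # 2 of 4
  expect_equal(combinedDeafnessFrequency(gen, mt_overlap, n_cases = 4L),
               25.00)   # fully overlapping: union = max
  expect_equal(combinedDeafnessFrequency(gen, mt_disjoint[0, ], n_cases = 4L),
               summarizeGjb2(gen, 4L)$pathogenic_carrier_freq)
})
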