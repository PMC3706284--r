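# Independent oracles and small fixture helpers shared by the tests.

# exhaustive global-alignment score under the same affine model as the
# implementation: recursion over all alignments, tracking the gap state so a
# run opening is charged exactly once
bruteAlignScore <- function(q, r, match = 1, mismatch = -1, gap_open = -2,
                            gap = -2) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  nq <- length(qc)
  nr <- length(rc)
  rec <- function(i, j, prev) {
    if (i > nq && j > nr) return(0)
    best <- -Inf
    if (i <= nq && j <= nr) {
      s <- if (qc[i] == rc[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= nq) {
      best <- max(best, gap + (if (prev == "X") 0 else gap_open) +
                    rec(i + 1L, j, "X"))
    }
    if (j <= nr) {
      best <- max(best, gap + (if (prev == "Y") 0 else gap_open) +
                    rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# exhaustive maximum base-pair count: enumerates every nested structure by
# either leaving the smallest available position unpaired or pairing it with
# each admissible partner, recursing on the inside and outside independently
bruteFoldMax <- function(seq, min_loop = 3L) {
  s <- gsub("T", "U", toupper(seq), fixed = TRUE)
  b <- strsplit(s, "")[[1]]
  canp <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(avail) {
    if (length(avail) == 0L) return(0L)
    i <- avail[1]
    rest <- avail[-1]
    best <- rec(rest)
    for (j in rest) {
      if (j - i > min_loop && canp(b[i], b[j])) {
        best <- max(best, 1L + rec(rest[rest > i & rest < j]) +
                      rec(rest[rest > j]))
      }
    }
    best
  }
  rec(seq_len(length(b)))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# the embedded catalogue, loaded once per test file
testCatalogue <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- loadCatalogue()
    cache
  }
})

# canonical genotype keys for a fixture table with allele1/allele2 columns
genotypeKeys <- function(tab) {
  vapply(seq_len(nrow(tab)), function(i) {
    canonicalGenotypeKey(tab$allele1[i], tab$allele2[i])
  }, character(1))
}

# conservation profile reproducing the embedded mitochondrial CI values on
# the synthetic 12S reference (fully conserved elsewhere)
mtConservationProfile <- function(catalogue) {
  refs <- referenceSetOf(catalogue)
  t4 <- fixtureTables(catalogue, "mt_variants")
  defs <- variantDefinitions(catalogue)
  off <- mtOffset(refs) - 1L
  profile <- rep(22L, length(mt12sSeq(refs)))
  pos <- defs$position[match(t4$name, defs$name)]
  profile[pos - off] <- t4$ci_matches
  list(profile = profile, positions = pos, offset = off)
}
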