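# Synthetic cohort and alignment generators: self-contained inputs whose
# downstream statistics are known by construction.

#' Apply a variant to a reference sequence
#'
#' Plants a single catalogued edit into a reference, checking that the
#' reference allele matches the sequence at the target position.  Insertions
#' are placed so their first inserted base assumes `position`.
#'
#' @param reference reference sequence (character or DNAString), in the
#'   coordinate frame of the call minus `coordinate_offset`
#' @param call one-row call data.frame ([variantCall()] or a row of
#'   [variantDefinitions()])
#' @param coordinate_offset locus coordinate of index 0 (0 for GJB2,
#'   `mtOffset(refs) - 1` for the 12S locus)
#' @return the edited sequence (character)
#' @examples
#' plantVariant("ACGT", variantCall("GJB2", "substitution", 2, "C", "T"))
#' @export
plantVariant <- function(reference, call, coordinate_offset = 0L) {
  s <- as.character(reference)
  stopifnot(nrow(call) == 1L)
  p <- call$position - as.integer(coordinate_offset)
  if (p < 1L || p > nchar(s) + 1L) {
    stop("variant position outside reference: ", call$name)
  }
  ref <- call$ref_allele
  if (nzchar(ref) && substr(s, p, p + nchar(ref) - 1L) != ref) {
    stop(sprintf("reference allele mismatch for %s: expected %s, found %s",
                 call$name, ref, substr(s, p, p + nchar(ref) - 1L)))
  }
  before <- substr(s, 1L, p - 1L)
  after <- substr(s, p + nchar(ref), nchar(s))
  paste0(before, call$alt_allele, after)
}

#' @describeIn plantVariant apply several variants (distinct, non-adjacent
#'   positions), right-most first so coordinates stay valid
#' @param calls data.frame of calls
#' @export
plantVariants <- function(reference, calls, coordinate_offset = 0L) {
  s <- as.character(reference)
  if (nrow(calls) == 0L) return(s)
  for (r in order(calls$position, decreasing = TRUE)) {
    s <- plantVariant(s, calls[r, , drop = FALSE], coordinate_offset)
  }
  s
}

#' Cohort generation specification
#'
#' Group sizes, the GJB2 genotype stratum counts, the mitochondrial
#' per-variant carrier counts, and the RNG seed.  Defaults (via
#' [cohortSpecFromCatalogue()]) are the study conditions: 658 cases with
#' moderate-to-profound nonsyndromic hearing loss, 462 normal-hearing
#' controls, genotype and carrier counts from the embedded tables.
#'
#' @param n_cases,n_controls group sizes
#' @param genotype_counts data.frame like the embedded genotype table
#'   (`allele1`, `allele2`, `stratum`, `case_count`, `control_count`);
#'   subjects not covered by any stratum carry no GJB2 variant
#' @param mt_variant_counts data.frame with `name`, `case_count`,
#'   `control_count`
#' @param seed integer RNG seed
#' @return list of class `"cohort_spec"`
#' @export
cohortSpec <- function(n_cases, n_controls, genotype_counts,
                       mt_variant_counts, seed = 1L) {
  if (sum(genotype_counts$case_count) > n_cases ||
      sum(genotype_counts$control_count) > n_controls) {
    stop("genotype stratum counts exceed group size")
  }
  if (any(mt_variant_counts$case_count > n_cases) ||
      any(mt_variant_counts$control_count > n_controls)) {
    stop("mitochondrial carrier counts exceed group size")
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 genotype_counts = genotype_counts,
                 mt_variant_counts = mt_variant_counts,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @describeIn cohortSpec the study conditions taken from the embedded tables
#' @param catalogue a [ScreenCatalogue-class]
#' @export
cohortSpecFromCatalogue <- function(catalogue, seed = 1L) {
  cohortSpec(658L, 462L,
             fixtureTables(catalogue, "genotypes"),
             fixtureTables(catalogue, "mt_variants")[
               , c("name", "case_count", "control_count")],
             seed = seed)
}

.split_allele <- function(a) {
  setdiff(trimws(strsplit(a, ",", fixed = TRUE)[[1]]), c("-", ""))
}

# sample mitochondrial carriers for one group under the documented constraints
.assign_mt <- function(ids, counts, defs, forbidden_for_pathogenic) {
  carried <- vector("list", length(ids))   # positions carried, per subject
  names(carried) <- ids
  out <- list()
  for (r in seq_len(nrow(counts))) {
    k <- counts$count[r]
    if (k == 0L) next
    v <- counts$name[r]
    d <- defs[defs$name == v & defs$locus == "MT12S", ]
    if (nrow(d) != 1L) stop("mitochondrial variant not in definitions: ", v)
    pos <- d$position
    # no subject may carry two variants at the same or adjacent positions
    # (adjacent substitutions would merge into a single MNV call)
    elig <- vapply(carried, function(p) !length(p) || all(abs(p - pos) > 1L),
                   logical(1))
    if (v %in% c("m.1555A>G", "m.1494C>T")) {
      elig <- elig & !(ids %in% forbidden_for_pathogenic)
    }
    cand <- ids[elig]
    if (length(cand) < k) {
      stop("not enough eligible subjects for ", v, " (need ", k, ")")
    }
    chosen <- if (length(cand) == k) cand else sample(cand, k)
    for (s in chosen) carried[[s]] <- c(carried[[s]], pos)
    if (v %in% c("m.1555A>G", "m.1494C>T")) {
      forbidden_for_pathogenic <- c(forbidden_for_pathogenic, chosen)
    }
    out[[v]] <- chosen
  }
  out
}

.band_range <- list(normal = c(5L, 20L), mild = c(26L, 40L),
                    moderate = c(41L, 60L), severe = c(61L, 80L),
                    profound = c(81L, 110L))

# four audiogram thresholds with an exact target pure-tone average
.audiogram_for <- function(band) {
  rng <- .band_range[[band]]
  target <- sample(seq(rng[1], rng[2]), 1L)
  j <- sample(-3:3, 4L, replace = TRUE)
  j <- j - mean(j)
  target + j
}

#' Generate a synthetic screening cohort
#'
#' Builds subjects and their sequencing records so that exactly the specified
#' number of subjects per GJB2 genotype stratum carry the planted variants,
#' and per-variant mitochondrial carrier counts are met exactly.  Each
#' nuclear subject receives two GJB2 coding-region allele sequences and one
#' promoter/exon-1 record; every subject receives one homoplasmic
#' mitochondrial sequence.  Case audiograms reproduce the embedded
#' genotype-phenotype severity distribution of their stratum; controls are
#' normal hearing.  Aminoglycoside-deafness mitochondrial mutations
#' (m.1555A>G, m.1494C>T) are assigned to case subjects without pathogenic
#' GJB2 genotypes, and no subject carries two mitochondrial variants at the
#' same or adjacent positions.  Deterministic under the spec's seed.
#'
#' @param spec a [cohortSpec()]
#' @param refs a [ReferenceSet-class]
#' @param catalogue a [ScreenCatalogue-class] (variant definitions and the
#'   phenotype table)
#' @return list with `subjects` (metadata data.frame), `records` (sequence
#'   records as in [readFastaRecords()]), and `truth` (the planted genotype
#'   and mitochondrial carrier assignments, for parameter-recovery checks)
#' @export
generateCohort <- function(spec, refs, catalogue) {
  stopifnot(inherits(spec, "cohort_spec"))
  defs <- variantDefinitions(catalogue)
  pheno <- fixtureTables(catalogue, "phenotypes")
  with_seed(spec$seed, {
    ids_case <- sprintf("P%04d", seq_len(spec$n_cases))
    ids_ctrl <- sprintf("C%04d", seq_len(spec$n_controls))

    gt <- spec$genotype_counts
    stratum_of <- function(ids, counts) {
      lab <- rep(NA_integer_, length(ids))
      nxt <- 1L
      for (r in seq_len(nrow(gt))) {
        k <- counts[r]
        if (k > 0L) {
          lab[nxt:(nxt + k - 1L)] <- r
          nxt <- nxt + k
        }
      }
      lab
    }
    strat_case <- stratum_of(ids_case, gt$case_count)
    strat_ctrl <- stratum_of(ids_ctrl, gt$control_count)

    # severity / onset for cases, per stratum, matching the phenotype table
    pheno_key <- vapply(seq_len(nrow(pheno)), function(i) {
      canonicalGenotypeKey(pheno$allele1[i], pheno$allele2[i])
    }, character(1))
    sev_case <- character(spec$n_cases)
    ons_case <- character(spec$n_cases)
    for (r in c(seq_len(nrow(gt)), NA_integer_)) {
      idx <- if (is.na(r)) which(is.na(strat_case)) else which(strat_case == r)
      if (!length(idx)) next
      key <- if (is.na(r)) "-/-" else
        canonicalGenotypeKey(gt$allele1[r], gt$allele2[r])
      ph <- pheno[match(key, pheno_key), ]
      n <- length(idx)
      if (!is.na(ph$n[1]) && ph$n == n) {
        sev <- rep(c("moderate", "severe", "profound"),
                   c(ph$moderate, ph$severe, ph$profound))
        ons <- rep(c("postlingual", "prelingual", "unknown"),
                   c(ph$onset_post, ph$onset_pre, ph$onset_unknown))
      } else {
        sev <- sample(c("moderate", "severe", "profound"), n, replace = TRUE)
        ons <- sample(c("prelingual", "postlingual"), n, replace = TRUE,
                      prob = c(0.8, 0.2))
      }
      sev_case[idx] <- sev
      ons_case[idx] <- ons
    }

    audio <- function(bands) {
      t(vapply(bands, .audiogram_for, numeric(4)))
    }
    aud_case <- audio(sev_case)
    aud_ctrl <- audio(rep("normal", spec$n_controls))

    sexes <- function(n, prop_f) {
      nf <- round(n * prop_f)
      sample(rep(c("F", "M"), c(nf, n - nf)))
    }
    ages <- function(n, mean, sd, lo, hi) {
      pmin(pmax(round(rnorm(n, mean, sd)), lo), hi)
    }

    subjects <- data.frame(
      subject_id = c(ids_case, ids_ctrl),
      group = rep(c("case", "control"), c(spec$n_cases, spec$n_controls)),
      sex = c(sexes(spec$n_cases, 344 / 658), sexes(spec$n_controls, 235 / 462)),
      age = c(ages(spec$n_cases, 11.3, 2.6, 2L, 45L),
              ages(spec$n_controls, 11.5, 2.9, 8L, 34L)),
      thr_500 = c(aud_case[, 1], aud_ctrl[, 1]),
      thr_1000 = c(aud_case[, 2], aud_ctrl[, 2]),
      thr_2000 = c(aud_case[, 3], aud_ctrl[, 3]),
      thr_4000 = c(aud_case[, 4], aud_ctrl[, 4]),
      onset = c(ons_case, rep("unknown", spec$n_controls)),
      aminoglycoside_exposure = FALSE,
      stringsAsFactors = FALSE)

    # mitochondrial carrier assignment
    mt <- spec$mt_variant_counts
    gjb2_path_ids <- ids_case[!is.na(strat_case) &
      gt$stratum[strat_case] %in% c("pathogenic_monoallelic",
                                    "pathogenic_biallelic")]
    mt_case <- .assign_mt(ids_case,
                          data.frame(name = mt$name, count = mt$case_count),
                          defs, gjb2_path_ids)
    mt_ctrl <- .assign_mt(ids_ctrl,
                          data.frame(name = mt$name, count = mt$control_count),
                          defs, character())
    mt_truth <- rbind(
      do.call(rbind, lapply(names(mt_case), function(v) {
        data.frame(subject_id = mt_case[[v]], group = "case", name = v,
                   stringsAsFactors = FALSE)
      })),
      do.call(rbind, lapply(names(mt_ctrl), function(v) {
        data.frame(subject_id = mt_ctrl[[v]], group = "control", name = v,
                   stringsAsFactors = FALSE)
      })))
    if (is.null(mt_truth)) {
      mt_truth <- data.frame(subject_id = character(), group = character(),
                             name = character(), stringsAsFactors = FALSE)
    }

    # a history of aminoglycoside exposure for three of the m.1494C>T carriers
    expo <- utils::head(mt_case[["m.1494C>T"]], 3L)
    subjects$aminoglycoside_exposure <- subjects$subject_id %in% expo

    # sequences
    gref <- as.character(gjb2Cds(refs))
    eref <- as.character(promoterExon1(refs))
    mref <- as.character(mt12sSeq(refs))
    moff <- mtOffset(refs) - 1L
    def_row <- function(v) {
      d <- defs[defs$name == v, ]
      if (nrow(d) != 1L) stop("genotype variant not in definitions: ", v)
      d
    }
    allele_seq <- function(names) {
      if (!length(names)) return(gref)
      plantVariants(gref, do.call(rbind, lapply(names, def_row)))
    }
    allele_cache <- new.env(parent = emptyenv())
    allele_seq_cached <- function(names) {
      key <- paste0("k:", paste(names, collapse = ","))
      if (is.null(allele_cache[[key]])) allele_cache[[key]] <- allele_seq(names)
      allele_cache[[key]]
    }

    all_ids <- subjects$subject_id
    strat_all <- c(strat_case, strat_ctrl)
    mt_by_subject <- split(mt_truth$name, mt_truth$subject_id)

    rec_subject <- rep(all_ids, each = 4L)
    rec_locus <- rep(c("GJB2", "GJB2", "GJB2_EX1", "MT12S"), length(all_ids))
    rec_allele <- rep(c("1", "2", "1", "mito"), length(all_ids))
    rec_seq <- character(length(rec_subject))
    for (i in seq_along(all_ids)) {
      r <- strat_all[i]
      a1 <- if (is.na(r)) character() else .split_allele(gt$allele1[r])
      a2 <- if (is.na(r)) character() else .split_allele(gt$allele2[r])
      mtv <- mt_by_subject[[all_ids[i]]]
      mseq <- if (is.null(mtv)) mref else
        plantVariants(mref, do.call(rbind, lapply(mtv, def_row)),
                      coordinate_offset = moff)
      base <- (i - 1L) * 4L
      rec_seq[base + 1L] <- allele_seq_cached(a1)
      rec_seq[base + 2L] <- allele_seq_cached(a2)
      rec_seq[base + 3L] <- eref
      rec_seq[base + 4L] <- mseq
    }
    records <- data.frame(
      id = paste(rec_subject, rec_locus, rec_allele, sep = "|"),
      subject_id = rec_subject, locus = rec_locus, allele_index = rec_allele,
      sequence = rec_seq, stringsAsFactors = FALSE)

    geno_truth <- data.frame(
      subject_id = all_ids,
      group = subjects$group,
      allele1 = ifelse(is.na(strat_all), "-", gt$allele1[strat_all]),
      allele2 = ifelse(is.na(strat_all), "-", gt$allele2[strat_all]),
      stratum = ifelse(is.na(strat_all), "none", gt$stratum[strat_all]),
      stringsAsFactors = FALSE)

    list(subjects = subjects, records = records,
         truth = list(genotypes = geno_truth, mt_carriers = mt_truth))
  })
}

#' Generate a multi-species ortholog alignment with configured conservation
#'
#' Builds an ungapped alignment of `n_species` rows over the human reference
#' row such that the number of rows carrying the human base in column `j`
#' equals `conservation_profile[j]` exactly (the human row always matches
#' itself, so the minimum is 1).  Non-matching species draw uniformly from
#' the three alternative bases.  Deterministic under `seed`.
#'
#' @param human_row human reference sequence (character or DNAString)
#' @param conservation_profile integer vector, one target match count per
#'   position, values in `[1, n_species]`
#' @param n_species number of alignment rows (default 22 primates, human
#'   included)
#' @param seed integer RNG seed
#' @return [Biostrings::DNAStringSet] of aligned rows; first row
#'   `Homo_sapiens`
#' @export
generateMsa <- function(human_row, conservation_profile, n_species = 22L,
                        seed = 1L) {
  human_row <- as.character(human_row)
  L <- nchar(human_row)
  stopifnot(length(conservation_profile) == L)
  if (any(conservation_profile < 1L | conservation_profile > n_species)) {
    stop("conservation profile values must lie in [1, n_species]")
  }
  with_seed(seed, {
    hb <- strsplit(human_row, "")[[1]]
    m <- matrix("", nrow = n_species, ncol = L)
    m[1, ] <- hb
    for (j in seq_len(L)) {
      k <- conservation_profile[j] - 1L           # non-human matching rows
      others <- seq(2L, n_species)
      match_rows <- if (k > 0L) sample(others, k) else integer()
      m[match_rows, j] <- hb[j]
      alt <- setdiff(c("A", "C", "G", "T"), hb[j])
      non <- setdiff(others, match_rows)
      m[non, j] <- sample(alt, length(non), replace = TRUE)
    }
    rows <- apply(m, 1L, paste, collapse = "")
    msa <- Biostrings::DNAStringSet(rows)
    names(msa) <- c("Homo_sapiens",
                    sprintf("primate_%02d", seq(2L, n_species)))
    msa
  })
}
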