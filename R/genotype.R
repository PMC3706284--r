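# Per-subject GJB2 genotype classes and audiometric severity banding.

#' Pure-tone average
#'
#' Arithmetic mean of the four better-ear thresholds at the speech
#' frequencies 0.5, 1, 2 and 4 kHz.
#'
#' @param thresholds numeric vector of four dB thresholds, or a data.frame /
#'   matrix with four columns (one row per subject)
#' @return numeric pure-tone average(s) in dB
#' @examples
#' ptaAverage(c(30, 40, 50, 60))  # 45
#' @export
ptaAverage <- function(thresholds) {
  if (is.data.frame(thresholds) || is.matrix(thresholds)) {
    m <- as.matrix(thresholds)
    if (ncol(m) != 4L) stop("four thresholds are required")
    if (anyNA(m)) stop("missing threshold")
    return(rowMeans(m))
  }
  if (length(thresholds) != 4L || anyNA(thresholds)) {
    stop("four thresholds are required")
  }
  mean(thresholds)
}

#' Band hearing severity from a pure-tone average
#'
#' Banding rule: below 26 dB normal; 26-40 dB mild; above 40 up to 60 dB
#' moderate; above 60 up to 80 dB severe; above 80 dB profound.  Non-integer
#' averages are classified on the real line (40.5 dB is moderate since mild
#' ends at 40).
#'
#' @param pta numeric pure-tone average(s), dB (non-negative)
#' @return character vector of bands
#' @examples
#' classifySeverity(c(35, 80, 81, 10))
#' @export
classifySeverity <- function(pta) {
  stopifnot(all(pta >= 0))
  cut(pta, breaks = c(-Inf, 26 - 1e-9, 40, 60, 80, Inf), right = TRUE,
      labels = c("normal", "mild", "moderate", "severe", "profound")) |>
    as.character()
}

.GCLASSES <- c("biallelic_homozygous", "biallelic_compound_het", "monoallelic",
               "polymorphism_or_unknown_only", "none")

#' Assign the GJB2 genotype class of a subject
#'
#' Only variants of catalogue category *pathogenic* count toward the
#' pathogenic allele number; polymorphisms and variants of unknown
#' significance never do.  Two pathogenic alleles with identical variant sets
#' are homozygous, with different sets compound heterozygous; one is
#' monoallelic; none with any other variant present is
#' `polymorphism_or_unknown_only`; otherwise `none`.
#'
#' @param allele1,allele2 character vectors of variant names carried in cis
#'   on each allele (empty vector or `"-"` for wild type)
#' @param catalogue a [ScreenCatalogue-class]
#' @param subject_id optional id carried through to the output
#' @return one-row data.frame: `subject_id`, `allele1`, `allele2`
#'   (comma-separated), `gclass`
#' @examples
#' cat <- loadCatalogue()
#' assignGenotype("c.235delC", "c.235delC", cat)$gclass
#' @export
assignGenotype <- function(allele1, allele2, catalogue,
                           subject_id = NA_character_) {
  norm <- function(a) {
    if (length(a) == 1L && !is.na(a)) a <- strsplit(a, ",", fixed = TRUE)[[1]]
    sort(setdiff(trimws(a), c("-", "", NA)))
  }
  a1 <- norm(allele1)
  a2 <- norm(allele2)
  ann <- variantAnnotations(catalogue)
  is_path <- function(v) {
    idx <- match(v, ann$name[ann$locus == "GJB2"])
    cats <- ann$category[ann$locus == "GJB2"][idx]
    cats[is.na(cats)] <- "novel"
    v[cats == "pathogenic"]
  }
  p1 <- is_path(a1)
  p2 <- is_path(a2)
  np <- (length(p1) > 0L) + (length(p2) > 0L)
  gclass <- if (np == 2L) {
    if (identical(p1, p2)) "biallelic_homozygous" else "biallelic_compound_het"
  } else if (np == 1L) {
    "monoallelic"
  } else if (length(a1) + length(a2) > 0L) {
    "polymorphism_or_unknown_only"
  } else {
    "none"
  }
  data.frame(subject_id = subject_id,
             allele1 = if (length(a1)) paste(a1, collapse = ",") else "-",
             allele2 = if (length(a2)) paste(a2, collapse = ",") else "-",
             gclass = gclass, stringsAsFactors = FALSE)
}

#' Cross-tabulate GJB2 genotypes against severity and onset
#'
#' Counts case subjects per genotype stratum and severity band / onset.  The
#' strata partition the case cohort (row sums of the severity columns equal
#' the stratum sizes).
#'
#' @param genotypes data.frame with `subject_id`, `allele1`, `allele2` (as
#'   from [assignGenotype()] or [screenCohort()])
#' @param subjects subject metadata (columns `subject_id`, `group`,
#'   `thr_500`, `thr_1000`, `thr_2000`, `thr_4000`, `onset`); only case
#'   subjects are tabulated
#' @return data.frame with `allele1`, `allele2`, `n`, severity band counts
#'   and onset counts, ordered by descending `n`
#' @export
crosstabGenotypePhenotype <- function(genotypes, subjects) {
  cases <- subjects[subjects$group == "case", ]
  g <- genotypes[match(cases$subject_id, genotypes$subject_id), ]
  if (nrow(cases) == 0L) {
    return(data.frame(allele1 = character(), allele2 = character(),
                      n = integer(), mild = integer(), moderate = integer(),
                      severe = integer(), profound = integer(),
                      onset_post = integer(), onset_pre = integer(),
                      onset_unknown = integer(), stringsAsFactors = FALSE))
  }
  pta <- ptaAverage(cases[, c("thr_500", "thr_1000", "thr_2000", "thr_4000")])
  sev <- classifySeverity(pta)
  key <- vapply(seq_len(nrow(g)), function(i) {
    canonicalGenotypeKey(g$allele1[i], g$allele2[i])
  }, character(1))
  out <- do.call(rbind, lapply(unique(key), function(k) {
    sel <- key == k
    al <- strsplit(k, "/", fixed = TRUE)[[1]]
    data.frame(allele1 = al[1], allele2 = al[2], n = sum(sel),
               mild = sum(sel & sev == "mild"),
               moderate = sum(sel & sev == "moderate"),
               severe = sum(sel & sev == "severe"),
               profound = sum(sel & sev == "profound"),
               onset_post = sum(sel & cases$onset == "postlingual"),
               onset_pre = sum(sel & cases$onset == "prelingual"),
               onset_unknown = sum(sel & cases$onset == "unknown"),
               stringsAsFactors = FALSE)
  }))
  out[order(-out$n, out$allele1), , drop = FALSE]
}
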