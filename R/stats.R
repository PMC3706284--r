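# Cohort-level carrier counts, frequencies and aggregates.

#' Round half away from zero
#'
#' Frequencies in this package are rounded half-up (`0.005 -> 0.01`), the
#' convention under which every printed percentage of the embedded tables is
#' reproduced exactly; base R's `round()` rounds half to even.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @examples
#' roundHalfUp(5.9270, 2)  # 5.93
#' @export
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Carrier frequency
#'
#' Subject-level carrier frequency in percent: `count / n * 100`, rounded
#' half-up to `digits` decimal places.  A subject carrying a variant on one
#' or both alleles counts once.
#'
#' @param count carrier count(s), `0 <= count <= n`
#' @param n group size (> 0)
#' @param digits rounding precision (default 2)
#' @return percent frequency
#' @examples
#' carrierFrequency(102, 658)  # 15.50
#' @export
carrierFrequency <- function(count, n, digits = 2L) {
  if (length(n) != 1L || n <= 0L) stop("group size must be a positive number")
  if (any(count < 0L) || any(count > n)) stop("count must lie in [0, n]")
  roundHalfUp(count / n * 100, digits)
}

#' Tally per-variant subject carriers in cases and controls
#'
#' @param carriers long data.frame with `subject_id`, `group`
#'   (`"case"`/`"control"`) and `name` (one row per subject-variant; duplicate
#'   rows are collapsed so a subject counts once per variant)
#' @param n_cases,n_controls group sizes (denominators)
#' @param variant_order optional character vector fixing the row order; names
#'   absent from `carriers` get zero counts
#' @return data.frame of class `"cohort_table"`: `name`, `case_carriers`,
#'   `case_freq`, `control_carriers`, `control_freq`; group sizes as
#'   attributes `n_cases` / `n_controls`
#' @export
tallyCarriers <- function(carriers, n_cases, n_controls,
                          variant_order = NULL) {
  u <- unique(carriers[, c("subject_id", "group", "name")])
  nm <- if (is.null(variant_order)) sort(unique(u$name)) else variant_order
  cc <- vapply(nm, function(v) sum(u$name == v & u$group == "case"), integer(1))
  nc <- vapply(nm, function(v) sum(u$name == v & u$group == "control"),
               integer(1))
  out <- data.frame(name = nm, case_carriers = cc,
                    case_freq = carrierFrequency(cc, n_cases),
                    control_carriers = nc,
                    control_freq = carrierFrequency(nc, n_controls),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_cases") <- as.integer(n_cases)
  attr(out, "n_controls") <- as.integer(n_controls)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Summarize pathogenic GJB2 genotype classes in the case group
#'
#' @param genotypes data.frame with `gclass` for case subjects (as from
#'   [screenCohort()], already restricted to cases or carrying a `group`
#'   column to restrict on)
#' @param n_cases case group size
#' @return list: `n_biallelic`, `n_homozygous`, `n_compound_het`,
#'   `n_monoallelic`, `n_pathogenic_carriers`, `pathogenic_carrier_freq`
#' @export
summarizeGjb2 <- function(genotypes, n_cases) {
  if (!is.null(genotypes$group)) {
    genotypes <- genotypes[genotypes$group == "case", ]
  }
  n_hom <- sum(genotypes$gclass == "biallelic_homozygous")
  n_chet <- sum(genotypes$gclass == "biallelic_compound_het")
  n_mono <- sum(genotypes$gclass == "monoallelic")
  list(n_biallelic = n_hom + n_chet,
       n_homozygous = n_hom,
       n_compound_het = n_chet,
       n_monoallelic = n_mono,
       n_pathogenic_carriers = n_hom + n_chet + n_mono,
       pathogenic_carrier_freq = carrierFrequency(n_hom + n_chet + n_mono,
                                                  n_cases))
}

#' Aggregate case carriers over several variants
#'
#' Sums the per-variant case carrier counts of the named rows of a cohort
#' table and expresses the sum as a percent of the case group.  Because a
#' subject can carry two of the named variants, the sum can exceed the
#' subject-level union ([combinedDeafnessFrequency()] uses union semantics
#' instead).
#'
#' @param table a cohort table from [tallyCarriers()]
#' @param names variant names to aggregate (must be rows of `table`)
#' @return list: `count` (summed carriers), `freq` (percent of cases)
#' @examples
#' \dontrun{aggregateVariants(tab, c("c.235delC", "c.299delAT"))}
#' @export
aggregateVariants <- function(table, names) {
  idx <- match(names, table$name)
  if (anyNA(idx)) {
    stop("variant not present in table: ", names[is.na(idx)][1])
  }
  count <- sum(table$case_carriers[idx])
  list(count = count, freq = carrierFrequency(count, attr(table, "n_cases")))
}

#' Combined deafness-mutation carrier rate
#'
#' Percent of case subjects carrying a pathogenic GJB2 genotype (monoallelic
#' or biallelic) or one of the listed mitochondrial mutations — the size of
#' the subject-level union, so overlapping carrier sets are not counted
#' twice.
#'
#' @param genotypes data.frame with `subject_id`, `group`, `gclass`
#' @param mt_profiles long data.frame with `subject_id`, `group`, `name`
#'   (mitochondrial carriers)
#' @param mt_names mitochondrial mutation names to include (default the two
#'   aminoglycoside-deafness mutations)
#' @param n_cases case group size
#' @return percent of cases, half-up 2 dp
#' @export
combinedDeafnessFrequency <- function(genotypes, mt_profiles,
                                      mt_names = c("m.1555A>G", "m.1494C>T"),
                                      n_cases) {
  g <- genotypes[genotypes$group == "case" & genotypes$gclass %in%
                   c("biallelic_homozygous", "biallelic_compound_het",
                     "monoallelic"), ]
  m <- mt_profiles[mt_profiles$group == "case" &
                     mt_profiles$name %in% mt_names, ]
  carriers <- union(g$subject_id, m$subject_id)
  carrierFrequency(length(carriers), n_cases)
}
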