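# End-to-end screen: sequence records -> calls -> genotypes -> cohort tables.

#' Screen a cohort of sequence records
#'
#' Calls variants in every record (aligning each distinct sequence once),
#' assembles per-subject GJB2 genotypes from the two allele records, collects
#' the mitochondrial variant profile of every subject, and keeps any calls in
#' the promoter/exon-1 amplicon separate (none are expected there).
#'
#' @param records sequence records ([readFastaRecords()] /
#'   [generateCohort()]`$records`)
#' @param subjects subject metadata with `subject_id` and `group`
#' @param refs a [ReferenceSet-class]
#' @param catalogue a [ScreenCatalogue-class]
#' @param config a [pipelineConfig()] (alignment scoring)
#' @return list of class `"deaf_screen"`: `genotypes` (subject_id, group,
#'   allele1, allele2, gclass), `mt_profiles` (subject_id, group, name),
#'   `exon1_calls`, `calls` (long per-record call table)
#' @export
screenCohort <- function(records, subjects, refs, catalogue,
                         config = pipelineConfig()) {
  stopifnot(all(c("subject_id", "locus", "allele_index", "sequence") %in%
                  names(records)))
  nuclear <- records$locus == "GJB2"
  bad <- tapply(records$allele_index[nuclear], records$subject_id[nuclear],
                function(a) length(a) > 2L)
  if (any(unlist(bad))) {
    stop("more than two GJB2 allele sequences for subject ",
         names(bad)[which(unlist(bad))[1]])
  }

  # align each distinct (locus, sequence) once
  key <- paste(records$locus, records$sequence, sep = "\r")
  uniq <- !duplicated(key)
  ucalls <- vector("list", sum(uniq))
  names(ucalls) <- key[uniq]
  for (k in which(uniq)) {
    ucalls[[key[k]]] <- callVariants(records$sequence[k], refs,
                                     records$locus[k],
                                     match = config$match,
                                     mismatch = config$mismatch,
                                     gap_open = config$gap_open,
                                     gap = config$gap)
  }
  .log_verbose("aligned %d distinct sequences for %d records",
               sum(uniq), nrow(records))

  calls <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    cl <- ucalls[[key[i]]]
    if (nrow(cl) == 0L) return(NULL)
    cbind(subject_id = records$subject_id[i],
          allele_index = records$allele_index[i], cl,
          stringsAsFactors = FALSE)
  }))
  if (is.null(calls)) {
    calls <- cbind(subject_id = character(), allele_index = character(),
                   .empty_calls())
  }

  grp <- subjects$group[match(records$subject_id, subjects$subject_id)]

  # GJB2 genotypes, one row per subject with nuclear records
  nuc_ids <- unique(records$subject_id[nuclear])
  genotypes <- do.call(rbind, lapply(nuc_ids, function(s) {
    a1 <- calls$name[calls$subject_id == s & calls$locus == "GJB2" &
                       calls$allele_index == "1"]
    a2 <- calls$name[calls$subject_id == s & calls$locus == "GJB2" &
                       calls$allele_index == "2"]
    assignGenotype(a1, a2, catalogue, subject_id = s)
  }))
  genotypes$group <- subjects$group[match(genotypes$subject_id,
                                          subjects$subject_id)]

  mt <- calls[calls$locus == "MT12S", c("subject_id", "name")]
  mt_profiles <- data.frame(
    subject_id = mt$subject_id,
    group = subjects$group[match(mt$subject_id, subjects$subject_id)],
    name = mt$name, stringsAsFactors = FALSE)

  exon1_calls <- calls[calls$locus == "GJB2_EX1", , drop = FALSE]

  structure(list(genotypes = genotypes, mt_profiles = mt_profiles,
                 exon1_calls = exon1_calls, calls = calls),
            class = "deaf_screen")
}

#' @export
print.deaf_screen <- function(x, ...) {
  cat(sprintf("deafness screen: %d genotyped subjects, %d mitochondrial carrier records\n",
              nrow(x$genotypes), nrow(x$mt_profiles)))
  print(table(x$genotypes$gclass))
  invisible(x)
}

# union of variant names over a subject's two alleles, as a long carrier table
.gjb2_carriers <- function(genotypes) {
  rows <- lapply(seq_len(nrow(genotypes)), function(i) {
    v <- unique(unlist(lapply(
      c(genotypes$allele1[i], genotypes$allele2[i]),
      function(a) setdiff(trimws(strsplit(a, ",", fixed = TRUE)[[1]]),
                          c("-", "")))))
    if (!length(v)) return(NULL)
    data.frame(subject_id = genotypes$subject_id[i],
               group = genotypes$group[i], name = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(), group = character(),
                      name = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Summarize a screened cohort
#'
#' Produces every cohort-level result of the screen: the per-variant GJB2 and
#' mitochondrial carrier tables (counts and percent frequencies in cases and
#' controls), the pathogenic GJB2 genotype summary, the genotype-phenotype
#' cross-tabulation, and the combined deafness-mutation carrier rate.
#'
#' @param screen result of [screenCohort()]
#' @param subjects subject metadata
#' @param catalogue a [ScreenCatalogue-class] (row ordering of the output
#'   tables)
#' @param n_cases,n_controls group sizes; default: counted from `subjects`
#' @param mt_pathogenic_names mitochondrial mutations entering the combined
#'   rate
#' @return list: `gjb2_table`, `mt_table`, `gjb2_summary`, `crosstab`,
#'   `combined_freq`
#' @export
summarizeScreen <- function(screen, subjects, catalogue,
                            n_cases = sum(subjects$group == "case"),
                            n_controls = sum(subjects$group == "control"),
                            mt_pathogenic_names = c("m.1555A>G", "m.1494C>T")) {
  ann <- variantAnnotations(catalogue)
  gjb2_table <- tallyCarriers(.gjb2_carriers(screen$genotypes),
                              n_cases, n_controls,
                              variant_order = ann$name[ann$locus == "GJB2"])
  mt_table <- tallyCarriers(screen$mt_profiles, n_cases, n_controls,
                            variant_order = ann$name[ann$locus == "MT12S"])
  list(gjb2_table = gjb2_table,
       mt_table = mt_table,
       gjb2_summary = summarizeGjb2(screen$genotypes, n_cases),
       crosstab = crosstabGenotypePhenotype(screen$genotypes, subjects),
       combined_freq = combinedDeafnessFrequency(
         screen$genotypes, screen$mt_profiles, mt_pathogenic_names, n_cases))
}
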