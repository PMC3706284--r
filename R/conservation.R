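# Multi-species conservation index and mitochondrial variant triage.

#' Map locus positions to alignment columns
#'
#' Every non-gap base of the reference row maps to exactly one column; gap
#' columns of the reference map to no position.
#'
#' @param msa [Biostrings::DNAStringSet] (or character vector) of aligned,
#'   equal-length rows
#' @param reference_row_id name (or index) of the reference row
#' @param coordinate_offset added to the reference base count to obtain locus
#'   coordinates (e.g. `mtOffset(refs) - 1` so column 1 maps to m.600)
#' @return data.frame with `position` and `column`
#' @export
mapMsaColumns <- function(msa, reference_row_id = "Homo_sapiens",
                          coordinate_offset = 0L) {
  rows <- as.character(msa)
  if (is.character(reference_row_id)) {
    if (!reference_row_id %in% names(rows)) {
      stop("reference row not found in alignment: ", reference_row_id)
    }
    ref <- rows[[reference_row_id]]
  } else {
    ref <- rows[[reference_row_id]]
  }
  chars <- strsplit(ref, "")[[1]]
  nongap <- chars != "-"
  data.frame(position = seq_len(sum(nongap)) + as.integer(coordinate_offset),
             column = which(nongap))
}

#' Conservation index of a position
#'
#' Number of alignment rows (the human reference included) carrying the
#' wild-type base at the column of the given position, over the total number
#' of rows, expressed as a half-up 1-dp percent and binned: `high` strictly
#' above `ci_high` percent, `mid` from `ci_low` to `ci_high` inclusive,
#' `low` below `ci_low`.  Gaps count as non-matching.
#'
#' @param msa aligned rows as in [mapMsaColumns()]
#' @param position locus position(s) to score
#' @param wildtype_base wild-type base(s); defaults to the reference row's
#'   base at the position
#' @param reference_row_id,coordinate_offset as in [mapMsaColumns()]
#' @param ci_high,ci_low bin thresholds in percent (defaults 78 / 50)
#' @return data.frame: `position`, `wildtype_base`, `matches`,
#'   `total_species`, `ci_percent`, `bin`
#' @examples
#' msa <- Biostrings::DNAStringSet(c(Homo_sapiens = "ACGT", sp2 = "ACGA"))
#' conservationIndex(msa, 4)
#' @export
conservationIndex <- function(msa, position, wildtype_base = NULL,
                              reference_row_id = "Homo_sapiens",
                              coordinate_offset = 0L,
                              ci_high = 78, ci_low = 50) {
  rows <- as.character(msa)
  map <- mapMsaColumns(msa, reference_row_id, coordinate_offset)
  col <- map$column[match(position, map$position)]
  if (anyNA(col)) {
    stop("position not mapped in alignment: ",
         position[is.na(col)][1])
  }
  chmat <- do.call(rbind, strsplit(unname(rows), ""))
  total <- nrow(chmat)
  wt <- if (is.null(wildtype_base)) {
    chmat[if (is.character(reference_row_id))
      match(reference_row_id, names(rows)) else reference_row_id, col]
  } else {
    rep_len(wildtype_base, length(position))
  }
  matches <- vapply(seq_along(col), function(i) {
    sum(chmat[, col[i]] == wt[i])
  }, integer(1))
  ci <- roundHalfUp(matches / total * 100, 1)
  bin <- ifelse(ci > ci_high, "high", ifelse(ci >= ci_low, "mid", "low"))
  data.frame(position = position, wildtype_base = wt, matches = matches,
             total_species = total, ci_percent = ci, bin = bin,
             stringsAsFactors = FALSE)
}

#' Count conservation-index bins
#'
#' @param records data.frame with a `bin` column (from [conservationIndex()])
#' @return named integer vector `c(n_high, n_mid, n_low)`
#' @export
summarizeCiBins <- function(records) {
  c(n_high = sum(records$bin == "high"),
    n_mid = sum(records$bin == "mid"),
    n_low = sum(records$bin == "low"))
}

#' Triage a mitochondrial 12S variant
#'
#' Classification rules, applied in priority order (exactly one fires):
#' \enumerate{
#'   \item name in the known deafness-mutation set (m.1555A>G, m.1494C>T,
#'     m.1095T>C and the position-961 variants; catalogue category
#'     *pathogenic*) — `known_pathogenic`.  Literature-derived labels take
#'     precedence, so m.1095T>C keeps its label despite a control carrier
#'     and the position-961 variants despite satisfying the putative rule.
#'   \item present in controls — `polymorphism`, regardless of conservation.
#'   \item absent from controls and conservation index above `ci_high`
#'     percent — `putative_deafness_associated`.
#'   \item otherwise `unclassified`.
#' }
#'
#' @param name variant name(s)
#' @param case_count,control_count subject carrier counts
#' @param ci_percent conservation index percent
#' @param catalogue a [ScreenCatalogue-class]
#' @param ci_high threshold in percent (default 78)
#' @return data.frame: `name`, `tclass`, `rule_fired`
#' @examples
#' cat <- loadCatalogue()
#' triageMtVariant("m.1222A>G", 1, 0, 100.0, cat)$tclass
#' @export
triageMtVariant <- function(name, case_count, control_count, ci_percent,
                            catalogue, ci_high = 78) {
  stopifnot(all(case_count >= 0), all(control_count >= 0))
  ann <- variantAnnotations(catalogue)
  known <- ann$name[ann$locus == "MT12S" & ann$category == "pathogenic"]
  n <- length(name)
  tclass <- character(n)
  rule <- character(n)
  for (i in seq_len(n)) {
    if (name[i] %in% known) {
      tclass[i] <- "known_pathogenic"
      rule[i] <- "known_pathogenic_set"
    } else if (control_count[i] > 0L) {
      tclass[i] <- "polymorphism"
      rule[i] <- "present_in_controls"
    } else if (ci_percent[i] > ci_high) {
      tclass[i] <- "putative_deafness_associated"
      rule[i] <- "absent_in_controls_and_high_CI"
    } else {
      tclass[i] <- "unclassified"
      rule[i] <- "no_rule_applies"
    }
  }
  data.frame(name = name, tclass = tclass, rule_fired = rule,
             stringsAsFactors = FALSE)
}

#' @describeIn triageMtVariant triage every row of a mitochondrial cohort
#'   table (columns `name`, `case_carriers`/`case_count`,
#'   `control_carriers`/`control_count`, `ci_percent`)
#' @param table mitochondrial variant table
#' @export
triageMtTable <- function(table, catalogue, ci_high = 78) {
  cc <- if ("case_carriers" %in% names(table)) table$case_carriers else
    table$case_count
  nc <- if ("control_carriers" %in% names(table)) table$control_carriers else
    table$control_count
  ci <- if ("ci_percent" %in% names(table)) table$ci_percent else
    roundHalfUp(table$ci_matches / table$ci_total * 100, 1)
  triageMtVariant(table$name, cc, nc, ci, catalogue, ci_high)
}
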