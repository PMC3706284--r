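# Readers and writers for the formats the pipeline touches, plus config and
# logging helpers.

.log_verbose <- function(...) {
  if (isTRUE(getOption("deafscreen.verbose", FALSE))) {
    message("[deafscreen] ", sprintf(...))
  }
}

.parse_record_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop(sprintf("malformed FASTA header at record %d: %s (expected 'subject|locus|allele')",
                 bad[1], ids[bad[1]]))
  }
  subject <- vapply(parts, `[[`, character(1), 1L)
  locus <- vapply(parts, `[[`, character(1), 2L)
  allele <- vapply(parts, `[[`, character(1), 3L)
  if (any(!locus %in% .LOCI)) {
    stop("unknown locus in FASTA header: ", locus[!locus %in% .LOCI][1])
  }
  mism <- (locus == "MT12S") != (allele == "mito")
  if (any(mism)) {
    stop("allele index 'mito' must be used exactly for MT12S records (record ",
         which(mism)[1], ")")
  }
  data.frame(id = ids, subject_id = subject, locus = locus,
             allele_index = allele, stringsAsFactors = FALSE)
}

#' Read subject sequence records from FASTA
#'
#' Record ids must encode subject, locus and allele as
#' `"subject|locus|allele"` with allele `1`/`2` for nuclear loci and `mito`
#' for the mitochondrial locus.  Lowercase sequence is uppercased with a
#' warning; characters outside `{A,C,G,T,N}` are an error.
#'
#' @param path FASTA file
#' @return data.frame with columns `id`, `subject_id`, `locus`,
#'   `allele_index`, `sequence` (zero rows for an empty file)
#' @export
readFastaRecords <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    return(cbind(.parse_record_ids(character()),
                 data.frame(sequence = character(), stringsAsFactors = FALSE)))
  }
  seqs <- as.character(raw)
  if (any(grepl("[acgtn]", seqs))) {
    warning("lowercase bases found in ", path, ": uppercased")
    seqs <- toupper(seqs)
  }
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("sequence alphabet outside {A,C,G,T,N} in ", path)
  }
  ids <- sub("\\s.*$", "", names(raw))
  out <- .parse_record_ids(ids)
  out$sequence <- unname(seqs)
  .log_verbose("read %d records from %s", nrow(out), path)
  out
}

#' Write subject sequence records to FASTA
#'
#' Inverse of [readFastaRecords()]: `readFastaRecords(writeFastaRecords(x))`
#' is the identity on records.
#'
#' @param records data.frame as returned by [readFastaRecords()] (columns
#'   `subject_id`, `locus`, `allele_index`, `sequence`)
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFastaRecords <- function(records, path) {
  ids <- paste(records$subject_id, records$locus, records$allele_index,
               sep = "|")
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 70L)
  .log_verbose("wrote %d records to %s", nrow(records), path)
  invisible(path)
}

# locus coordinate -> reference string index conversion for anchoring
.vcf_anchor <- function(call, refs) {
  lr <- .locus_ref(refs, call$locus)
  p <- call$position - lr$offset
  if (p < 1L || p > nchar(lr$seq)) {
    stop("unmappable position for VCF output: ", call$name)
  }
  base_at <- function(i) substr(lr$seq, i, i)
  switch(call$kind,
    substitution = ,
    mnv_substitution = ,
    delins = list(pos = call$position, ref = call$ref_allele,
                  alt = call$alt_allele),
    deletion = {
      if (p == 1L) stop("cannot anchor deletion at reference start: ", call$name)
      list(pos = call$position - 1L,
           ref = paste0(base_at(p - 1L), call$ref_allele),
           alt = base_at(p - 1L))
    },
    insertion = {
      if (p == 1L) stop("cannot anchor insertion at reference start: ", call$name)
      list(pos = call$position - 1L,
           ref = base_at(p - 1L),
           alt = paste0(base_at(p - 1L), call$alt_allele))
    })
}

#' Write (and read back) a variant table
#'
#' Two dialects.  `"tsv"` keeps the legacy representation (locus, kind,
#' 1-based position of the first affected base, ref/alt allele strings, legacy
#' name, and the catalogue category when annotations are supplied).  `"vcf"`
#' emits minimal VCF 4.2: `CHROM` is the locus name, positions are 1-based,
#' and indels are written left-anchored on the preceding reference base, so a
#' deletion at position p becomes `POS = p-1` with a two-or-more-base `REF`.
#' Legacy names are carried in the `ID` column because several of them (e.g.
#' `c.605ins46`) are not valid HGVS and the name, not the VCF coordinates, is
#' the primary identifier of this screen.
#'
#' @param calls data.frame of normalized, named calls
#' @param path output file
#' @param dialect `"tsv"` or `"vcf"`
#' @param refs [ReferenceSet-class]; required for the VCF dialect (anchors)
#' @param annotations optional annotation table ([variantAnnotations()]) used
#'   to add a `category` column in the TSV dialect
#' @return `path`, invisibly
#' @export
writeVariantTable <- function(calls, path, dialect = c("tsv", "vcf"),
                              refs = NULL, annotations = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    out <- calls
    if (!is.null(annotations)) {
      key <- paste(annotations$locus, annotations$name)
      idx <- match(paste(out$locus, out$name), key)
      out$category <- ifelse(is.na(idx), "novel", annotations$category[idx])
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(refs)) stop("the VCF dialect needs a ReferenceSet for anchoring")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=deafscreen",
           sprintf("##contig=<ID=GJB2,length=%d>", length(gjb2Cds(refs))),
           sprintf("##contig=<ID=GJB2_EX1,length=%d>", length(promoterExon1(refs))),
           sprintf("##contig=<ID=MT12S,length=%d>", length(mt12sSeq(refs))),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  rows <- character(nrow(calls))
  for (r in seq_len(nrow(calls))) {
    a <- .vcf_anchor(calls[r, ], refs)
    rows[r] <- paste(calls$locus[r], a$pos, calls$name[r], a$ref, a$alt,
                     ".", "PASS", ".", sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @describeIn writeVariantTable read a variant table back into call records;
#'   VCF anchored indels are decoded to the legacy representation and
#'   positions re-normalized, so a TSV -> VCF -> TSV round trip preserves the
#'   normalized variant identity
#' @export
readVariantTable <- function(path, dialect = c("tsv", "vcf"), refs = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    out <- read.delim(path, stringsAsFactors = FALSE)
    if (nrow(out) == 0L) return(.empty_calls())
    out$ref_allele[is.na(out$ref_allele)] <- ""
    out$alt_allele[is.na(out$alt_allele)] <- ""
    return(out[, names(.empty_calls())])
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(.empty_calls())
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  calls <- .empty_calls()
  for (r in seq_len(nrow(f))) {
    locus <- f[r, 1]; pos <- as.integer(f[r, 2])
    ref <- f[r, 4]; alt <- f[r, 5]
    # strip the shared anchor prefix
    while (nchar(ref) > 0L && nchar(alt) > 0L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
           !(nchar(ref) == nchar(alt))) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
    }
    kind <- if (!nzchar(ref)) "insertion"
      else if (!nzchar(alt)) "deletion"
      else if (nchar(ref) == nchar(alt)) {
        if (nchar(ref) == 1L) "substitution" else "mnv_substitution"
      } else "delins"
    call <- data.frame(locus = locus, kind = kind, position = pos,
                       ref_allele = ref, alt_allele = alt,
                       name = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(refs)) {
      lr <- .locus_ref(refs, locus)
      call <- normalizeVariant(call, lr$seq, coordinate_offset = lr$offset)
    }
    call$name <- nameVariant(call)
    calls <- rbind(calls, call)
  }
  calls
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the screen: alignment scoring,
#' conservation-index bin thresholds (percent; `high` strictly above,
#' `mid` the closed interval down to `low`), rounding precision for
#' frequencies, the minimum hairpin loop for folding, and the RNG seed.
#'
#' @param ci_high,ci_low CI bin thresholds in percent (defaults 78 and 50;
#'   must be strictly ordered)
#' @param match,mismatch,gap_open,gap alignment scoring parameters
#' @param freq_digits rounding precision for percent frequencies
#' @param min_loop minimum hairpin loop length for [foldRna()]
#' @param seed integer RNG seed for the generators
#' @return list of class `"deaf_config"`
#' @export
pipelineConfig <- function(ci_high = 78, ci_low = 50, match = 1, mismatch = -1,
                           gap_open = -2, gap = -2, freq_digits = 2L,
                           min_loop = 3L, seed = 1L) {
  if (!(ci_low < ci_high)) stop("CI thresholds must satisfy ci_low < ci_high")
  structure(list(ci_high = ci_high, ci_low = ci_low, match = match,
                 mismatch = mismatch, gap_open = gap_open, gap = gap,
                 freq_digits = as.integer(freq_digits),
                 min_loop = as.integer(min_loop), seed = as.integer(seed)),
            class = "deaf_config")
}

#' @describeIn pipelineConfig read a configuration from a YAML file; keys
#'   missing from the file keep their defaults
#' @param path YAML file of flat keys
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}
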