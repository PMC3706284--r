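# Embedded variant catalogue: annotations, concrete variant definitions on the
# synthetic references, and the machine-readable study count tables.

# mitochondrial 12S variants with established deafness association in the
# literature: the aminoglycoside-deafness mutations and the position-961 group
.MT_KNOWN_PATHOGENIC <- c("m.1555A>G", "m.1494C>T", "m.1095T>C",
                          "m.961insC", "m.961delT+insC", "m.961T>C")

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "deafscreen")
  if (!nzchar(path)) stop("embedded resource not found: ", file)
  path
}

.read_fixture <- function(file) {
  read.delim(.extdata(file), comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Parse a legacy-style variant name
#'
#' Accepts the legacy nomenclature used throughout the package: coding (`c.`)
#' or mitochondrial (`m.`) prefix, a 1-based position, and a payload that is a
#' substitution (`G>A`, `TC>AA`), a deletion (`delC`, `del16`), an insertion
#' (`insAAGG`, `ins46`) or a deletion+insertion (`delT+insC`).
#'
#' @param name character(1) legacy variant name
#' @return list with `prefix`, `position`, `payload`
#' @examples
#' parseVariantName("c.235delC")
#' parseVariantName("m.1555A>G")
#' @export
parseVariantName <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec("^([cm])\\.([0-9]+)(.+)$", name))[[1]]
  if (length(m) == 0L) stop("malformed variant name: ", name)
  payload <- m[4]
  ok <- grepl("^[A-Z]+>[A-Z]+$", payload) ||
    grepl("^del([A-Z]+|[0-9]+)(\\+ins([A-Z]+|[0-9]+))?$", payload) ||
    grepl("^ins([A-Z]+|[0-9]+)$", payload)
  if (!ok) stop("malformed variant name: ", name)
  list(prefix = paste0(m[2], "."), position = as.integer(m[3]),
       payload = payload)
}

# position used for canonical ordering of variant names within genotype labels
.name_position <- function(name) {
  vapply(name, function(n) parseVariantName(n)$position, integer(1))
}

#' Canonical genotype key
#'
#' Renders a subject's two allele variant lists as a canonical label:
#' variants within an allele ordered by position, the allele with fewer
#' variants (ties: smaller first position) first, wild-type alleles as `"-"`.
#' Used to match genotype strata across the generator, the pipeline output and
#' the embedded phenotype table regardless of input ordering.
#'
#' @param allele1,allele2 character vectors of variant names (possibly empty),
#'   or single comma-separated strings; `"-"` and `""` denote wild type
#' @return character(1) canonical `allele1/allele2` label (`"-/-"` for no
#'   variants)
#' @examples
#' canonicalGenotypeKey("c.235delC", "c.35delG")
#' canonicalGenotypeKey(c("c.341A>G", "c.79G>A"), "c.341A>G")
#' @export
canonicalGenotypeKey <- function(allele1, allele2) {
  norm <- function(a) {
    if (length(a) == 1L) a <- strsplit(a, ",", fixed = TRUE)[[1]]
    a <- trimws(a[!a %in% c("-", "")])
    if (!length(a)) return(character())
    a[order(.name_position(a), a)]
  }
  a1 <- norm(allele1)
  a2 <- norm(allele2)
  key <- function(a) {
    if (!length(a)) c(Inf, Inf) else c(length(a), .name_position(a[1]))
  }
  k1 <- key(a1); k2 <- key(a2)
  if (k1[1] > k2[1] || (k1[1] == k2[1] && k1[2] > k2[2])) {
    tmp <- a1; a1 <- a2; a2 <- tmp
  }
  lab <- function(a) if (length(a)) paste(a, collapse = ",") else "-"
  paste(lab(a1), lab(a2), sep = "/")
}

.canonicalize_allele <- function(a) {
  vapply(a, function(x) {
    v <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    v <- v[!v %in% c("-", "")]
    if (!length(v)) "-" else paste(v[order(.name_position(v), v)], collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

# expand genotype strata into per-variant subject carrier counts: a subject
# carrying a variant on one or both alleles counts once
.carriers_from_genotypes <- function(genotab) {
  out <- list()
  for (i in seq_len(nrow(genotab))) {
    vars <- unique(unlist(lapply(
      c(genotab$allele1[i], genotab$allele2[i]),
      function(a) setdiff(trimws(strsplit(a, ",", fixed = TRUE)[[1]]), c("-", ""))
    )))
    for (v in vars) {
      if (is.null(out[[v]])) out[[v]] <- c(case = 0L, control = 0L)
      out[[v]] <- out[[v]] + c(genotab$case_count[i], genotab$control_count[i])
    }
  }
  data.frame(name = names(out),
             case_carriers = vapply(out, `[[`, integer(1), "case"),
             control_carriers = vapply(out, `[[`, integer(1), "control"),
             row.names = NULL, stringsAsFactors = FALSE)
}

.catalogue_integrity <- function(ann, defs, refs, tables) {
  fail <- function(tab, msg) {
    stop(sprintf("catalogue integrity error in %s: %s", tab, msg), call. = FALSE)
  }
  t1 <- tables$gjb2_variants
  t2 <- tables$genotypes
  t4 <- tables$mt_variants

  if (anyDuplicated(paste(ann$locus, ann$name))) {
    fail("annotations", "duplicated variant name within a locus")
  }
  if (sum(ann$locus == "GJB2" & ann$category == "pathogenic") != 9L) {
    fail("table1_gjb2_variants", "expected exactly 9 pathogenic GJB2 entries")
  }
  if (nrow(t4) != 30L) fail("table4_mt_variants", "expected exactly 30 rows")

  # every defined variant must sit inside its reference with the declared
  # wild-type bases
  for (i in seq_len(nrow(defs))) {
    lr <- .locus_ref(refs, defs$locus[i])
    p <- defs$position[i] - lr$offset
    ref <- defs$ref_allele[i]
    if (p < 1L || p + max(nchar(ref), 1L) - 1L > nchar(lr$seq)) {
      fail("variant_definitions", paste("position outside reference:", defs$name[i]))
    }
    if (nzchar(ref) && substr(lr$seq, p, p + nchar(ref) - 1L) != ref) {
      fail("variant_definitions",
           paste("reference base mismatch for", defs$name[i]))
    }
  }

  # genotype-table bookkeeping against the per-variant carrier table
  path <- t2[t2$stratum %in% c("pathogenic_monoallelic", "pathogenic_biallelic"), ]
  if (sum(path$case_count) != 164L) {
    fail("table2_genotypes", "pathogenic case strata must sum to 164")
  }
  if (sum(t2$case_count[t2$stratum == "pathogenic_monoallelic"]) != 70L ||
      sum(t2$case_count[t2$stratum == "pathogenic_biallelic"]) != 94L) {
    fail("table2_genotypes", "expected 70 monoallelic and 94 biallelic cases")
  }
  derived <- .carriers_from_genotypes(t2)
  pnames <- ann$name[ann$locus == "GJB2" & ann$category == "pathogenic"]
  for (v in pnames) {
    d <- derived[derived$name == v, ]
    p1 <- t1[t1$name == v, ]
    if (nrow(d) != 1L || nrow(p1) != 1L ||
        d$case_carriers != p1$case_carriers ||
        d$control_carriers != p1$control_carriers) {
      fail("table2_genotypes",
           paste("derived carrier count disagrees with table1 for", v))
    }
  }

  # printed frequencies must equal recomputed half-up percentages
  chk_freq <- function(tab, nm, count, freq, n) {
    bad <- which(roundHalfUp(count / n * 100, 2) != freq)
    if (length(bad)) fail(tab, paste("frequency column inconsistent at", nm[bad][1]))
  }
  chk_freq("table1_gjb2_variants", t1$name, t1$case_carriers, t1$case_freq, 658)
  chk_freq("table1_gjb2_variants", t1$name, t1$control_carriers, t1$control_freq, 462)
  chk_freq("table4_mt_variants", t4$name, t4$case_count, t4$case_freq, 658)
  chk_freq("table4_mt_variants", t4$name, t4$control_count, t4$control_freq, 462)

  invisible(TRUE)
}

#' Load the embedded screening catalogue
#'
#' Reads the packaged variant annotation tables, the concrete variant
#' definitions, the synthetic stand-in reference sequences and the four study
#' count tables, verifies their internal consistency (pathogenic carrier
#' counts derivable from the genotype strata must equal the per-variant
#' table; printed frequencies must equal recomputed ones; every defined
#' variant must sit on its reference), and returns a
#' [ScreenCatalogue-class].
#'
#' @return A [ScreenCatalogue-class] object.
#' @examples
#' cat <- loadCatalogue()
#' sum(variantAnnotations(cat)$category == "pathogenic" &
#'     variantAnnotations(cat)$locus == "GJB2")  # 9
#' @export
loadCatalogue <- function() {
  t1 <- .read_fixture("table1_gjb2_variants.tsv")
  t2 <- .read_fixture("table2_genotypes.tsv")
  t3 <- .read_fixture("table3_phenotypes.tsv")
  t4 <- .read_fixture("table4_mt_variants.tsv")
  defs <- .read_fixture("variant_definitions.tsv")
  defs$ref_allele[is.na(defs$ref_allele)] <- ""
  defs$alt_allele[is.na(defs$alt_allele)] <- ""

  fa <- function(f) as.character(Biostrings::readDNAStringSet(.extdata(f))[[1]])
  hdr <- names(Biostrings::readDNAStringSet(.extdata("mt12s_synthetic.fa")))[1]
  off <- as.integer(sub(".*offset=m\\.([0-9]+).*", "\\1", hdr))
  refs <- referenceSet(fa("gjb2_cds_synthetic.fa"), fa("mt12s_synthetic.fa"),
                       fa("gjb2_promoter_exon1_synthetic.fa"), mt_offset = off)

  # canonicalize allele spellings so genotype keys are order-independent
  t2$allele1 <- .canonicalize_allele(t2$allele1)
  t2$allele2 <- .canonicalize_allele(t2$allele2)
  t3$allele1 <- .canonicalize_allele(t3$allele1)
  t3$allele2 <- .canonicalize_allele(t3$allele2)

  ann_gjb2 <- data.frame(
    name = t1$name, locus = "GJB2", category = tolower(t1$category),
    domain_label = t1$domain, previously_reported = t1$previously_reported,
    polyphen_score = t1$polyphen_score, sift_score = t1$sift_score,
    aa_change = t1$aa_change, stringsAsFactors = FALSE)
  mt_cat <- ifelse(t4$name %in% .MT_KNOWN_PATHOGENIC, "pathogenic",
                   ifelse(t4$previously_reported, "unknown", "novel"))
  ann_mt <- data.frame(
    name = t4$name, locus = "MT12S", category = mt_cat, domain_label = "",
    previously_reported = t4$previously_reported,
    polyphen_score = NA_real_, sift_score = NA_real_, aa_change = "",
    stringsAsFactors = FALSE)
  ann <- rbind(ann_gjb2, ann_mt)

  tables <- list(gjb2_variants = t1, genotypes = t2, phenotypes = t3,
                 mt_variants = t4)
  .catalogue_integrity(ann, defs, refs, tables)
  new("ScreenCatalogue", annotations = ann, definitions = defs,
      references = refs, tables = tables)
}

#' Annotate a variant by its legacy name
#'
#' Looks a legacy-style variant name up in the catalogue.  Names absent from
#' the catalogue yield a novel-category annotation
#' (`previously_reported = FALSE`); syntactically invalid names are an error.
#'
#' @param name legacy variant name (e.g. `"c.235delC"`, `"m.1555A>G"`)
#' @param locus `"GJB2"` or `"MT12S"`
#' @param catalogue a [ScreenCatalogue-class] from [loadCatalogue()]
#' @return one-row data.frame with the annotation fields
#' @examples
#' cat <- loadCatalogue()
#' annotateVariant("c.235delC", "GJB2", cat)$category     # "pathogenic"
#' annotateVariant("m.1222A>G", "MT12S", cat)$previously_reported  # FALSE
#' @export
annotateVariant <- function(name, locus = c("GJB2", "MT12S"), catalogue) {
  locus <- match.arg(locus)
  parseVariantName(name)
  ann <- catalogue@annotations
  hit <- ann[ann$name == name & ann$locus == locus, ]
  if (nrow(hit) == 1L) return(hit)
  data.frame(name = name, locus = locus, category = "novel",
             domain_label = "", previously_reported = FALSE,
             polyphen_score = NA_real_, sift_score = NA_real_,
             aa_change = "", stringsAsFactors = FALSE)
}
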