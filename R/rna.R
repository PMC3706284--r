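# RNA secondary-structure prediction by base-pair maximization and
# structure comparison.  The folder is a deliberately coarse stand-in for a
# thermodynamic model: it maximizes the number of Watson-Crick / G·U pairs
# under a minimum-hairpin-loop constraint, which is sufficient to detect
# whether a variant changes the predicted pairing near its position.

#' Fold an RNA sequence by base-pair maximization
#'
#' Finds a nested structure with the maximum number of valid pairs
#' (Watson-Crick or G·U wobble, hairpin loops of at least `min_loop` unpaired
#' bases, no pseudoknots).  DNA input is transcribed (T to U).  The traceback
#' is deterministic: leaving the 5' base unpaired is preferred when optimal,
#' otherwise the smallest admissible partner is taken, so folds are invariant
#' to T/U spelling and reproducible across runs.
#'
#' @param sequence RNA or DNA sequence (character, DNAString or RNAString)
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3)
#' @return an [RnaStructure-class]
#' @examples
#' foldRna("GGGAAAACCC")  # 3 pairs
#' @export
foldRna <- function(sequence, min_loop = 3L) {
  s <- toupper(as.character(sequence))
  if (!nzchar(s)) stop("cannot fold an empty sequence")
  s <- gsub("T", "U", s, fixed = TRUE)
  if (grepl("[^ACGU]", s)) stop("sequence must be over {A,C,G,U} (or T)")
  pairs <- nussinov_cpp(s, as.integer(min_loop))
  db <- rep(".", nchar(s))
  if (nrow(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  new("RnaStructure", sequence = s, pairs = pairs,
      dot_bracket = paste(db, collapse = ""), min_loop = as.integer(min_loop))
}

#' Quantify the structural alteration a variant induces
#'
#' Base-pair distance between two predicted structures (the size of the
#' symmetric difference of their pair sets; zero iff the structures are
#' identical) plus a local report of positions near the variant whose pairing
#' partner changed.
#'
#' @param wt,mut [RnaStructure-class] objects for the wild-type and variant
#'   transcripts
#' @param variant_position 1-based position of the variant in the transcript
#' @param window half-width of the local report window (default 15)
#' @param indel set `TRUE` when the variant is an indel; otherwise differing
#'   sequence lengths are an error
#' @return list: `bp_distance` (integer), `altered` (logical,
#'   `bp_distance > 0`), `local_window_report` (data.frame `position`,
#'   `wt_partner`, `mut_partner`; `NA` = unpaired)
#' @examples
#' wt <- foldRna("GGGGAAAACCCC")
#' mu <- foldRna("GGGGAAAACCAC")
#' structureDelta(wt, mu, 11)$altered
#' @export
structureDelta <- function(wt, mut, variant_position, window = 15L,
                           indel = FALSE) {
  n_wt <- nchar(wt@sequence)
  n_mut <- nchar(mut@sequence)
  if (n_wt != n_mut && !indel) {
    stop("sequence lengths differ (", n_wt, " vs ", n_mut,
         ") but the variant is not an indel")
  }
  key <- function(p) if (nrow(p)) paste(p[, 1], p[, 2]) else character()
  k_wt <- key(wt@pairs)
  k_mut <- key(mut@pairs)
  bp_distance <- length(setdiff(k_wt, k_mut)) + length(setdiff(k_mut, k_wt))

  partner <- function(x, n) {
    out <- rep(NA_integer_, n)
    p <- x@pairs
    out[p[, 1]] <- p[, 2]
    out[p[, 2]] <- p[, 1]
    out
  }
  n <- max(n_wt, n_mut)
  pw <- partner(wt, n)
  pm <- partner(mut, n)
  win <- seq(max(1L, variant_position - window),
             min(n, variant_position + window))
  changed <- win[!(is.na(pw[win]) & is.na(pm[win])) &
                   (is.na(pw[win]) != is.na(pm[win]) |
                      (!is.na(pw[win]) & !is.na(pm[win]) &
                         pw[win] != pm[win]))]
  list(bp_distance = as.integer(bp_distance),
       altered = bp_distance > 0L,
       local_window_report = data.frame(
         position = changed,
         wt_partner = pw[changed],
         mut_partner = pm[changed]))
}
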