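## STR-based conceptus classification (forensic-style allele-sharing rules).

#' Classify a conceptus from mole and maternal STR profiles
#'
#' Applies the allele-sharing rules used in molecular mole diagnosis:
#' \itemize{
#'   \item if one or more loci of the villous tissue share no allele with
#'     the maternal alleles, the conceptus is androgenetic;
#'   \item an androgenetic conceptus with at least one locus showing two
#'     different alleles is androgenetic dispermic;
#'   \item an androgenetic conceptus with a single allele at every locus
#'     is androgenetic monospermic;
#'   \item any locus with three or more distinct alleles raises a triploid
#'     suspicion (peak-height dosage is deliberately not modelled);
#'   \item profiles sharing at least one allele with the mother at every
#'     locus are classified biparental diploid.
#' }
#' The sex marker is excluded from the rules. Fewer than
#' \code{min_shared_loci} loci typed in both profiles gives an
#' indeterminate call.
#'
#' @param mole,mother \code{str_profile} objects.
#' @param min_shared_loci minimum number of informative loci (default 8).
#' @return Object of class \code{conceptus_class} with elements
#'   \code{category}, \code{evidence} (per-locus data frame with allele
#'   counts and maternal-sharing flags) and \code{reason}.
#' @export
classify_conceptus <- function(mole, mother, min_shared_loci = 8) {
  stopifnot(inherits(mole, "str_profile"), inherits(mother, "str_profile"))
  loci <- setdiff(intersect(names(mole$alleles), names(mother$alleles)),
                  STR_SEX_MARKER)
  evidence <- data.frame(
    locus = loci,
    n_alleles = vapply(loci, function(l) length(mole$alleles[[l]]), 0L),
    maternal_shared = vapply(loci, function(l)
      length(intersect(mole$alleles[[l]], mother$alleles[[l]])) > 0, TRUE),
    stringsAsFactors = FALSE
  )
  rownames(evidence) <- NULL
  make <- function(category, reason = NA_character_) {
    structure(list(category = category, evidence = evidence,
                   reason = reason),
              class = "conceptus_class")
  }
  if (length(loci) < min_shared_loci)
    return(make("indeterminate",
                sprintf("only %d shared typed loci (need >= %d)",
                        length(loci), min_shared_loci)))
  if (any(evidence$n_alleles >= 3))
    return(make("triploid_suspect",
                paste("locus with >= 3 alleles:",
                      evidence$locus[evidence$n_alleles >= 3][1])))
  androgenetic <- any(!evidence$maternal_shared)
  if (androgenetic) {
    if (any(evidence$n_alleles == 2)) make("androgenetic_dispermic")
    else make("androgenetic_monospermic")
  } else {
    make("biparental_diploid")
  }
}

#' Count loci with exactly two distinct alleles
#'
#' The two-allelic locus count is the standard summary of STR zygosity in
#' mole work-ups: dispermic moles carry several, monospermic moles none.
#' The sex marker is excluded.
#'
#' @param profile an \code{str_profile}.
#' @return Integer count.
#' @export
count_biallelic_loci <- function(profile) {
  stopifnot(inherits(profile, "str_profile"))
  alleles <- profile$alleles[setdiff(names(profile$alleles),
                                     STR_SEX_MARKER)]
  sum(lengths(alleles) == 2L)
}

#' @export
print.conceptus_class <- function(x, ...) {
  cat("Conceptus class:", x$category, "\n")
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  cat("  loci:", nrow(x$evidence),
      "| unshared with mother:", sum(!x$evidence$maternal_shared),
      "| two-allelic:", sum(x$evidence$n_alleles == 2), "\n")
  invisible(x)
}
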