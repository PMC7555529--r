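## Selected-BAF parent-of-origin calling and mitochondrial identity checks.

.select_loci <- function(mole, mother, maternal_gtype) {
  stopifnot(inherits(mole, "snp_sample"), inherits(mother, "snp_sample"))
  idx <- match(mole$locus_id, mother$locus_id)
  shared <- !is.na(idx)
  coverage <- sum(shared) / max(nrow(mole), nrow(mother))
  if (coverage < 0.9)
    stop(sprintf(
      "mole and maternal samples share only %.0f%% of their loci",
      100 * coverage))
  mat_gt <- mother$gtype[idx]
  keep <- shared & !is.na(mat_gt) & mat_gt == maternal_gtype
  out <- data.frame(
    chromosome = mole$chromosome[keep],
    position = mole$position[keep],
    locus_id = mole$locus_id[keep],
    baf = mole$baf[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "maternal_gtype") <- maternal_gtype
  attr(out, "mole_id") <- mole$sample_id[1]
  attr(out, "mother_id") <- mother$sample_id[1]
  class(out) <- c("selected_baf", "data.frame")
  out
}

#' Select mole BAF at loci where the mother is AA
#'
#' The core of the selected-BAF duo procedure: restrict the mole's BAF
#' values to the loci at which the maternal blood sample was called
#' homozygous AA. At such loci any maternal homolog in the mole
#' contributes an A allele, capping the true BAF at \eqn{(n-1)/n < 1}; an
#' all-paternal chromosome keeps loci at BAF 1 wherever every paternal
#' homolog carries B. Loss of the BAF~1 band among selected loci
#' therefore marks maternal contribution. Maternal no-calls are excluded.
#'
#' @param mole,mother \code{snp_sample} tables typed on (mostly) the same
#'   loci; an error is raised when the duo shares less than 90\% of loci.
#' @return A \code{selected_baf} data frame with columns
#'   \code{chromosome}, \code{position}, \code{locus_id}, \code{baf}.
#' @export
select_loci_maternal_AA <- function(mole, mother) {
  .select_loci(mole, mother, "AA")
}

#' Mirror selection: loci where the mother is BB
#'
#' Diagnostic counterpart of [select_loci_maternal_AA()]: at maternal-BB
#' loci a maternal homolog caps the true BAF at \eqn{1/n > 0}, so loss of
#' the BAF~0 band carries the same information. Used as a consistency
#' cross-check, never as the primary decider.
#'
#' @inheritParams select_loci_maternal_AA
#' @return A \code{selected_baf} data frame.
#' @export
select_loci_maternal_BB <- function(mole, mother) {
  .select_loci(mole, mother, "BB")
}

#' Retention of the extreme BAF band among selected loci
#'
#' Computes the fraction of selected loci on a chromosome whose BAF lies
#' in the extreme band (\code{baf >= top_band_cut} for the maternal-AA /
#' top-band procedure; \code{baf <= 1 - top_band_cut} for the maternal-BB
#' mirror) and divides it by the fraction expected under the all-paternal
#' hypothesis. The expectation is computed analytically from the panel's
#' population allele frequencies: given maternal genotype AA at a locus
#' with B-allele frequency \eqn{p}, the probability that all \eqn{n}
#' paternal homologs carry B is \eqn{p^n}, weighted by the selection
#' probability \eqn{(1-p)^2}. Identity-by-descent between sperm of one
#' father makes the observed fraction exceed this independence baseline,
#' so the statistic is about 1 or above for all-paternal chromosomes and
#' collapses to 0 when a maternal homolog is present.
#'
#' @param selected a \code{selected_baf} set.
#' @param chromosome chromosome label.
#' @param panel the [locus_panel()] the duo was typed on (source of
#'   population allele frequencies).
#' @param copy_number called copy number of the chromosome.
#' @param top_band_cut BAF cut defining the extreme band.
#' @param min_selected minimum selected loci for a determinate statistic.
#' @param expected \code{"analytic"} (default) or \code{"empirical"}; the
#'   empirical mode replaces the analytic expectation by the median
#'   observed band fraction over the other autosomes in \code{selected},
#'   which assumes those are confidently all-paternal disomies.
#' @return List with \code{statistic}, \code{numerator} (observed band
#'   fraction), \code{expectation}, \code{n_selected}, \code{determined}
#'   and \code{reason}.
#' @export
top_band_retention <- function(selected, chromosome, panel, copy_number,
                               top_band_cut = 0.85, min_selected = 30L,
                               expected = c("analytic", "empirical")) {
  chromosome <- .stopifnot_scalar_chrom(chromosome)
  expected <- match.arg(expected)
  band <- attr(selected, "maternal_gtype")
  if (is.null(band)) band <- "AA"
  in_band <- function(baf) {
    if (band == "AA") baf >= top_band_cut else baf <= 1 - top_band_cut
  }
  band_fraction <- function(chrom) {
    baf <- selected$baf[selected$chromosome == chrom &
                          !is.na(selected$baf)]
    if (length(baf) < min_selected) return(NA_real_)
    mean(in_band(baf))
  }
  numerator <- band_fraction(chromosome)
  n_sel <- sum(selected$chromosome == chromosome & !is.na(selected$baf))
  if (is.na(numerator))
    return(list(statistic = NA_real_, numerator = NA_real_,
                expectation = NA_real_, n_selected = n_sel,
                determined = FALSE,
                reason = sprintf("only %d selected loci (need >= %d)",
                                 n_sel, min_selected)))
  if (expected == "analytic") {
    p <- panel$pop_b_freq[panel$chromosome == chromosome]
    if (band == "AA") {
      w <- (1 - p)^2
      expectation <- sum(w * p^copy_number) / sum(w)
    } else {
      w <- p^2
      expectation <- sum(w * (1 - p)^copy_number) / sum(w)
    }
  } else {
    others <- setdiff(intersect(unique(selected$chromosome), AUTOSOMES),
                      chromosome)
    fr <- vapply(others, band_fraction, 0)
    fr <- fr[!is.na(fr)]
    if (!length(fr))
      return(list(statistic = NA_real_, numerator = numerator,
                  expectation = NA_real_, n_selected = n_sel,
                  determined = FALSE,
                  reason = "no reference chromosomes for empirical mode"))
    expectation <- stats::median(fr)
  }
  list(statistic = numerator / expectation, numerator = numerator,
       expectation = expectation, n_selected = n_sel, determined = TRUE,
       reason = NA_character_)
}

#' Call the parental origin of a chromosome's homologs
#'
#' Applies [top_band_retention()] at the called copy number and compares
#' the statistic with \code{loss_threshold}: a statistic below the
#' threshold means the BAF~1 band is lost among maternal-AA loci, i.e.
#' the chromosome carries a maternal homolog. On a trisomic chromosome
#' the extra homolog is then called maternal (otherwise paternal); on a
#' disomic chromosome maternal contribution flags a biparental disomy.
#'
#' @param mole,mother \code{snp_sample} tables (ignored when
#'   \code{selected} is supplied).
#' @param chromosome_call a \code{chromosome_call} from
#'   [call_copy_number()]; must be unambiguous.
#' @param panel the [locus_panel()] of the duo.
#' @param loss_threshold retention statistic below which the extreme band
#'   counts as lost.
#' @param top_band_cut,min_selected passed to [top_band_retention()].
#' @param selected optionally a precomputed
#'   [select_loci_maternal_AA()] result, to avoid re-selection when
#'   calling many chromosomes.
#' @return Object of class \code{origin_call} with fields
#'   \code{chromosome}, \code{copy_number}, \code{maternal_contribution},
#'   \code{extra_origin} (\code{"maternal"}, \code{"paternal"},
#'   \code{"n/a"} or \code{"undetermined"}), \code{biparental_disomy},
#'   \code{retention} and the thresholds used.
#' @export
call_origin <- function(mole, mother, chromosome_call, panel,
                        loss_threshold = 0.25, top_band_cut = 0.85,
                        min_selected = 30L, selected = NULL) {
  stopifnot(inherits(chromosome_call, "chromosome_call"))
  if (chromosome_call$ambiguous)
    stop("cannot call origin on an ambiguous copy-number call (",
         chromosome_call$reason, ")")
  if (is.null(selected)) selected <- select_loci_maternal_AA(mole, mother)
  chrom <- chromosome_call$chromosome
  n <- chromosome_call$copy_number
  ret <- top_band_retention(selected, chrom, panel, n,
                            top_band_cut = top_band_cut,
                            min_selected = min_selected)
  if (!ret$determined) {
    return(structure(list(
      chromosome = chrom, copy_number = n,
      maternal_contribution = NA, extra_origin = "undetermined",
      biparental_disomy = NA, retention = ret,
      loss_threshold = loss_threshold, top_band_cut = top_band_cut),
      class = "origin_call"))
  }
  maternal <- ret$statistic < loss_threshold
  structure(list(
    chromosome = chrom, copy_number = n,
    maternal_contribution = maternal,
    extra_origin = if (n >= 3) {
      if (maternal) "maternal" else "paternal"
    } else "n/a",
    biparental_disomy = (n == 2) && maternal,
    retention = ret,
    loss_threshold = loss_threshold, top_band_cut = top_band_cut),
    class = "origin_call")
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf(
    "chr %s (copy %s): %s [retention %.3f = %.4f / %.4f, n=%d]\n",
    x$chromosome, x$copy_number,
    if (isTRUE(x$maternal_contribution)) "maternal contribution"
    else if (isFALSE(x$maternal_contribution)) "all-paternal"
    else "undetermined",
    x$retention$statistic, x$retention$numerator,
    x$retention$expectation, x$retention$n_selected))
  invisible(x)
}

#' Mitochondrial SNP identity across samples
#'
#' Mole tissue inherits the maternal mitochondria, so a mole and its
#' mother must carry identical MT genotypes; a mismatch indicates a
#' sample swap. Loci with the same genotype in every sample carry no
#' information and are excluded: the informative loci are those with at
#' least two distinct called genotypes across the cohort. Pairwise
#' identity is exact genotype agreement at all informative loci,
#' ignoring no-calls.
#'
#' @param samples list of \code{snp_sample} tables (at least two for a
#'   non-trivial comparison) that include MT loci.
#' @return List with \code{informative_loci}, \code{n_informative},
#'   \code{identity} (logical sample-by-sample matrix) and
#'   \code{genotypes} (informative-locus genotype matrix).
#' @export
mito_identity <- function(samples) {
  stopifnot(length(samples) >= 1)
  ids <- vapply(samples, function(s) s$sample_id[1], "")
  mt <- lapply(samples, function(s) {
    rows <- s$chromosome == "MT"
    if (!any(rows)) stop("sample ", s$sample_id[1], " has no MT loci")
    stats::setNames(s$gtype[rows], s$locus_id[rows])
  })
  loci <- sort(unique(unlist(lapply(mt, names))))
  geno <- vapply(mt, function(g) unname(g[loci]), character(length(loci)))
  if (is.vector(geno)) geno <- matrix(geno, nrow = length(loci))
  dimnames(geno) <- list(loci, ids)
  informative <- apply(geno, 1, function(g) {
    g <- g[!is.na(g)]
    length(unique(g)) >= 2
  })
  info_loci <- loci[informative]
  gi <- geno[informative, , drop = FALSE]
  k <- length(ids)
  identity <- matrix(TRUE, k, k, dimnames = list(ids, ids))
  if (k > 1 && length(info_loci)) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      a <- gi[, i]; b <- gi[, j]
      ok <- !is.na(a) & !is.na(b)
      same <- all(a[ok] == b[ok])
      identity[i, j] <- identity[j, i] <- same
    }
  }
  list(informative_loci = info_loci, n_informative = length(info_loci),
       identity = identity, genotypes = gi)
}
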