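## Per-chromosome copy-number calling from BAF band structure and LRR shift.

#' Theoretical BAF band model for a copy-number hypothesis
#'
#' At copy number \eqn{n} the possible allelic states are \eqn{k} B alleles
#' out of \eqn{n}, so the theoretical BAF levels are \eqn{k/n} for
#' \eqn{k = 0..n}: \{0, 1\} bands are always present, disomy adds 0.5,
#' trisomy adds 1/3 and 2/3, tetrasomy 1/4, 1/2 and 3/4.
#'
#' @param copy_number hypothesised copy number, 1..4.
#' @param tolerance half-width of a band window in BAF units; must be
#'   smaller than half the minimal gap between levels.
#' @param min_occupancy minimum fraction of chromosome loci for a band to
#'   count as present.
#' @param min_loci minimum absolute locus count for band presence.
#' @return Object of class \code{band_model}.
#' @export
band_model <- function(copy_number, tolerance = 0.08, min_occupancy = 0.02,
                       min_loci = 10L) {
  stopifnot(copy_number %in% 1:4)
  levels <- (0:copy_number) / copy_number
  if (copy_number > 1 && tolerance >= 1 / (2 * copy_number))
    stop("tolerance must be below half the minimal inter-level gap")
  structure(list(copy_number = copy_number, levels = levels,
                 tolerance = tolerance, min_occupancy = min_occupancy,
                 min_loci = as.integer(min_loci)),
            class = "band_model")
}

#' BAF band occupancies on one chromosome
#'
#' For each theoretical level of the model, the fraction of non-missing
#' loci whose BAF falls within the band window. A band is flagged present
#' when its occupancy reaches both the fractional and the absolute
#' minimum.
#'
#' @param sample a \code{snp_sample}.
#' @param chromosome chromosome label.
#' @param model a [band_model()].
#' @param min_total minimum number of non-missing loci required for a
#'   usable profile.
#' @return List with \code{occupancy} (named numeric), \code{present}
#'   (named logical), \code{n_loci}, \code{ok} and \code{reason}.
#' @export
baf_band_profile <- function(sample, chromosome, model,
                             min_total = 50L) {
  chromosome <- .stopifnot_scalar_chrom(chromosome)
  baf <- sample$baf[sample$chromosome == chromosome & !is.na(sample$baf)]
  nm <- as.character(round(model$levels, 3))
  if (length(baf) < min_total) {
    occ <- stats::setNames(rep(NA_real_, length(model$levels)), nm)
    return(list(occupancy = occ, present = stats::setNames(
      rep(NA, length(model$levels)), nm),
      n_loci = length(baf), ok = FALSE,
      reason = sprintf("only %d non-missing loci (need >= %d)",
                       length(baf), min_total)))
  }
  occ <- vapply(model$levels, function(l)
    mean(abs(baf - l) <= model$tolerance), 0)
  names(occ) <- nm
  present <- occ >= model$min_occupancy &
    occ * length(baf) >= model$min_loci
  names(present) <- nm
  list(occupancy = occ, present = present, n_loci = length(baf),
       ok = TRUE, reason = NA_character_)
}

# expected LRR at copy n under attenuation a
.expected_lrr <- function(n, attenuation = 1) attenuation * log2(n / 2)

#' Call the copy number of one chromosome
#'
#' Combines BAF band structure with the LRR shift. Intermediate-band
#' presence nominates copy-number hypotheses (bands near 1/3 and 2/3 for
#' trisomy; 1/4 and 3/4 for tetrasomy; 0.5 alone is compatible with
#' balanced disomy or tetrasomy; bands only at 0/1 leave all hypotheses
#' open, as happens when all homologs are identical). The median LRR then
#' selects among the nominated hypotheses by proximity to the expected
#' shift \eqn{a \log_2(n/2)}; a trisomy call additionally requires the
#' median LRR to exceed \code{lrr_gain_threshold}, and a call is declared
#' ambiguous when BAF and LRR disagree (median LRR further than
#' \code{lrr_margin} from every nominated expectation, or two nominated
#' expectations both within 0.05).
#'
#' @param sample a \code{snp_sample}.
#' @param chromosome chromosome label.
#' @param tolerance,min_occupancy,min_loci band-model parameters.
#' @param lrr_attenuation attenuation assumed for expected LRR shifts.
#' @param lrr_gain_threshold minimum median LRR for a gain call; defaults
#'   to half the expected trisomy shift.
#' @param lrr_margin maximum distance between the median LRR and the
#'   chosen hypothesis's expectation.
#' @param min_total minimum non-missing loci.
#' @return Object of class \code{chromosome_call}: chromosome, copy number
#'   (\code{NA} when ambiguous), \code{ambiguous} flag, band occupancies,
#'   LRR median/mean, locus count and reason.
#' @export
call_copy_number <- function(sample, chromosome, tolerance = 0.08,
                             min_occupancy = 0.02, min_loci = 10L,
                             lrr_attenuation = 1,
                             lrr_gain_threshold =
                               0.5 * lrr_attenuation * log2(1.5),
                             lrr_margin = 0.3, min_total = 50L) {
  chromosome <- .stopifnot_scalar_chrom(chromosome)
  models <- lapply(1:4, band_model, tolerance = tolerance,
                   min_occupancy = min_occupancy, min_loci = min_loci)
  profs <- lapply(models, function(m)
    baf_band_profile(sample, chromosome, m, min_total = min_total))
  rows <- sample$chromosome == chromosome
  lrr <- sample$lrr[rows & !is.na(sample$lrr)]
  lrr_median <- stats::median(lrr)
  lrr_mean <- mean(lrr)
  res <- function(copy, ambiguous, reason = NA_character_) {
    structure(list(
      chromosome = chromosome, copy_number = copy, ambiguous = ambiguous,
      occupancy = profs[[3]]$occupancy, profiles = profs,
      lrr_median = lrr_median, lrr_mean = lrr_mean,
      n_loci = profs[[1]]$n_loci, reason = reason),
      class = "chromosome_call")
  }
  if (!profs[[1]]$ok) return(res(NA_integer_, TRUE, profs[[1]]$reason))

  mid_present <- function(n) {
    p <- profs[[n]]$present
    all(p[-c(1, length(p))])
  }
  candidates <-
    if (mid_present(3) || mid_present(4)) c(3L, 4L)[c(mid_present(3),
                                                      mid_present(4))]
    else if (mid_present(2)) c(2L, 4L)
    else 1:4
  expect <- .expected_lrr(candidates, lrr_attenuation)
  dist <- abs(lrr_median - expect)
  if (length(candidates) > 1 && sum(dist <= 0.05) > 1)
    return(res(NA_integer_, TRUE,
               "LRR consistent with more than one nominated copy number"))
  pick <- candidates[which.min(dist)]
  if (min(dist) > lrr_margin)
    return(res(NA_integer_, TRUE, sprintf(
      "BAF bands nominate copy %s but median LRR %.3f matches none",
      paste(candidates, collapse = "/"), lrr_median)))
  if (pick >= 3 && lrr_median <= lrr_gain_threshold)
    return(res(NA_integer_, TRUE,
               "gain-like BAF bands without the expected LRR shift"))
  res(pick, FALSE)
}

#' Call the sex-chromosome constitution
#'
#' Y presence is decided by the Y-locus call rate (absent Y chromosomes
#' render as no-calls); X and Y copy numbers then come from median LRR
#' proximity to the expected shifts for one, two or three copies.
#'
#' @param sample a \code{snp_sample}.
#' @param y_presence_threshold minimum Y call rate for Y presence.
#' @param lrr_attenuation assumed LRR attenuation.
#' @return A string such as \code{"XX"}, \code{"XY"}, \code{"XYY"},
#'   \code{"XXYY"}.
#' @export
call_sex <- function(sample, y_presence_threshold = 0.5,
                     lrr_attenuation = 1) {
  x_rows <- sample$chromosome == "X"
  y_rows <- sample$chromosome == "Y"
  if (!any(x_rows) || !any(y_rows))
    stop("sample has no sex-chromosome loci")
  copy_from_lrr <- function(rows, max_copy = 3) {
    lrr <- sample$lrr[rows & !is.na(sample$lrr)]
    cand <- seq_len(max_copy)
    cand[which.min(abs(stats::median(lrr) -
                         .expected_lrr(cand, lrr_attenuation)))]
  }
  y_call_rate <- mean(!is.na(sample$gtype[y_rows]))
  n_y <- if (y_call_rate >= y_presence_threshold)
    copy_from_lrr(y_rows, max_copy = 2) else 0L
  n_x <- copy_from_lrr(x_rows, max_copy = 3)
  paste0(strrep("X", n_x), strrep("Y", n_y))
}

#' Assemble a molecular karyotype estimate
#'
#' Calls every autosome with [call_copy_number()] and the sex constitution
#' with [call_sex()], then renders an ISCN-like string such as
#' \code{"47,XY,+13"} or \code{"48,XX,+7,+11"}. Any ambiguous autosome
#' leaves the estimate flagged non-confident (its copy number is counted
#' as 2 in the total).
#'
#' @param sample a \code{snp_sample}.
#' @param ... passed on to [call_copy_number()].
#' @return Object of class \code{karyotype_estimate} with fields
#'   \code{total}, \code{sex}, \code{gains}, \code{losses},
#'   \code{string}, \code{confident} and the per-chromosome \code{calls}.
#' @export
estimate_karyotype <- function(sample, ...) {
  chroms <- intersect(AUTOSOMES, unique(sample$chromosome))
  calls <- lapply(chroms, function(ch) call_copy_number(sample, ch, ...))
  names(calls) <- chroms
  copies <- vapply(calls, function(x)
    if (is.na(x$copy_number)) 2L else x$copy_number, 0L)
  sex <- call_sex(sample)
  gains <- unlist(lapply(chroms, function(ch)
    rep(ch, max(0L, copies[[ch]] - 2L))))
  losses <- chroms[copies < 2L]
  total <- sum(copies) + nchar(sex)
  string <- paste0(
    total, ",", sex,
    if (length(gains)) paste0(",", paste0("+", gains, collapse = ",")) else "",
    if (length(losses)) paste0(",", paste0("-", losses, collapse = ",")) else ""
  )
  structure(list(
    total = total, sex = sex, gains = gains, losses = losses,
    string = string,
    confident = !any(vapply(calls, `[[`, TRUE, "ambiguous")),
    calls = calls),
    class = "karyotype_estimate")
}

#' @export
print.karyotype_estimate <- function(x, ...) {
  cat("Estimated karyotype:", x$string,
      if (!x$confident) "(non-confident)" else "", "\n")
  invisible(x)
}

#' Per-chromosome LRR location summary
#'
#' Median and mean LRR per autosome; trisomic chromosomes shift to larger
#' values than disomic ones, which is the diagnostic used to corroborate
#' BAF-based gain calls.
#'
#' @param sample a \code{snp_sample}.
#' @return Data frame with columns \code{chromosome}, \code{lrr_median},
#'   \code{lrr_mean}, \code{n_loci}.
#' @export
lrr_shift_summary <- function(sample) {
  chroms <- intersect(AUTOSOMES, unique(sample$chromosome))
  rows <- lapply(chroms, function(ch) {
    lrr <- sample$lrr[sample$chromosome == ch & !is.na(sample$lrr)]
    data.frame(chromosome = ch, lrr_median = stats::median(lrr),
               lrr_mean = mean(lrr), n_loci = length(lrr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
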