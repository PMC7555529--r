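## Cohort-level aggregation and exact testing.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the probability-ordering convention: the
#' sum of hypergeometric probabilities (computed in log space) of all
#' tables with the observed margins whose probability does not exceed
#' that of the observed table (within a relative tolerance of 1e-7 for
#' ties), the convention used by common statistical software. A table
#' with a zero margin has no alternative configurations; its p-value is 1
#' by convention and a warning is issued.
#'
#' @param table 2x2 matrix (or length-4 vector, filled column-wise) of
#'   non-negative integer counts.
#' @return The two-sided p-value as a plain number.
#' @export
fisher_exact <- function(table) {
  x <- as.vector(as.matrix(table))
  if (length(x) != 4 || any(x < 0) || any(x != round(x)))
    stop("'table' must be four non-negative integer counts")
  a <- x[1]; c_ <- x[2]; b <- x[3]; d <- x[4]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    warning("zero margin: p = 1 by convention")
    return(1)
  }
  k <- seq(max(0, c1 - r2), min(r1, c1))
  logp <- stats::dhyper(k, c1, c2, r1, log = TRUE)
  log_obs <- stats::dhyper(a, c1, c2, r1, log = TRUE)
  min(1, sum(exp(logp[logp <= log_obs + 1e-7])))
}

#' Aggregate per-case calls into a cohort report
#'
#' @param cases list of per-case call lists as produced by
#'   [analyze_duo()] (fields \code{id}, \code{karyotype},
#'   \code{extra_origins}, \code{biparental_disomies}, \code{aneuploid},
#'   \code{maternal_contribution}, \code{outcome}).
#' @return Object of class \code{cohort_report}: a per-case data frame
#'   plus aggregate counts (euploid/aneuploid cases, maternal- and
#'   paternal-origin extra chromosomes, biparental disomies, overall GTN
#'   incidence). Aggregates are direct counts over the rows, so the
#'   report is order-invariant. Duplicate case IDs are an error.
#' @export
summarize_cohort <- function(cases) {
  ids <- vapply(cases, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate case ID: ", ids[anyDuplicated(ids)])
  fmt_extras <- function(x) {
    if (!length(x)) return("")
    paste(paste0(names(x), ":", unname(x)), collapse = ";")
  }
  rows <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(
      id = cs$id,
      karyotype = if (is.null(cs$karyotype)) NA_character_
                  else cs$karyotype$string,
      extra_origins = fmt_extras(cs$extra_origins),
      biparental_disomies = paste(cs$biparental_disomies, collapse = ";"),
      aneuploid = isTRUE(cs$aneuploid),
      maternal_contribution = isTRUE(cs$maternal_contribution),
      outcome = if (is.null(cs$outcome) || is.na(cs$outcome))
        NA_character_ else cs$outcome,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(rows))
    rows <- data.frame(id = character(), karyotype = character(),
                       extra_origins = character(),
                       biparental_disomies = character(),
                       aneuploid = logical(),
                       maternal_contribution = logical(),
                       outcome = character(), stringsAsFactors = FALSE)
  rows <- rows[order(rows$id), , drop = FALSE]
  rownames(rows) <- NULL
  all_extras <- unlist(lapply(cases, `[[`, "extra_origins"))
  n_bipar <- sum(vapply(cases, function(cs)
    length(cs$biparental_disomies), 0L))
  gtn <- sum(rows$outcome == "GTN", na.rm = TRUE)
  n_out <- sum(!is.na(rows$outcome))
  structure(list(
    cases = rows,
    n_cases = nrow(rows),
    n_euploid = sum(!rows$aneuploid),
    n_aneuploid = sum(rows$aneuploid),
    n_maternal_extras = sum(all_extras == "maternal"),
    n_paternal_extras = sum(all_extras == "paternal"),
    n_biparental_disomies = n_bipar,
    gtn = list(count = gtn, n = n_out,
               incidence = if (n_out) gtn / n_out else NA_real_)),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "Cohort of %d cases: %d euploid, %d aneuploid; extras %d maternal / %d paternal; %d biparental disomies\n",
    x$n_cases, x$n_euploid, x$n_aneuploid, x$n_maternal_extras,
    x$n_paternal_extras, x$n_biparental_disomies))
  if (x$gtn$n)
    cat(sprintf("GTN: %d/%d (%.0f%%)\n", x$gtn$count, x$gtn$n,
                100 * x$gtn$incidence))
  invisible(x)
}

#' GTN incidence stratified by maternal contribution
#'
#' A case belongs to the maternal-contribution stratum when any of its
#' chromosomes carries a maternal homolog: a maternal-origin extra
#' chromosome or a biparental disomy.
#'
#' @param report a [summarize_cohort()] result.
#' @return Data frame with one row per stratum (\code{with_maternal},
#'   \code{without_maternal}) and columns \code{n}, \code{gtn},
#'   \code{incidence}.
#' @export
gtn_stratification <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  rows <- report$cases[!is.na(report$cases$outcome), ]
  strat <- function(sel, label) {
    data.frame(stratum = label, n = sum(sel),
               gtn = sum(rows$outcome[sel] == "GTN"),
               incidence = if (sum(sel)) mean(rows$outcome[sel] == "GTN")
                           else NA_real_,
               stringsAsFactors = FALSE)
  }
  mc <- rows$maternal_contribution
  rbind(strat(mc, "with_maternal"), strat(!mc, "without_maternal"))
}
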