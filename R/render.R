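## Rendering simulated genomes into SNP-array samples and STR profiles.

#' Array noise model
#'
#' @param baf_sd standard deviation of additive Gaussian BAF noise.
#' @param lrr_sd standard deviation of additive Gaussian LRR noise.
#' @param lrr_attenuation multiplicative compression of the ideal LRR
#'   (real platforms report log R ratios shrunk towards 0); in (0, 1].
#' @param missing_rate fraction of loci rendered as no-calls.
#' @return Object of class \code{noise_model}.
#' @export
noise_model <- function(baf_sd = 0.03, lrr_sd = 0.15, lrr_attenuation = 1,
                        missing_rate = 0.005) {
  if (baf_sd < 0 || lrr_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (lrr_attenuation <= 0 || lrr_attenuation > 1)
    stop("lrr_attenuation must lie in (0, 1]")
  structure(list(baf_sd = baf_sd, lrr_sd = lrr_sd,
                 lrr_attenuation = lrr_attenuation,
                 missing_rate = missing_rate),
            class = "noise_model")
}

.new_snp_sample <- function(sample_id, panel, gtype, baf, lrr) {
  out <- data.frame(
    sample_id = sample_id,
    locus_id = panel$locus_id,
    chromosome = panel$chromosome,
    position = panel$position,
    gtype = gtype,
    baf = baf,
    lrr = lrr,
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_sample", "data.frame")
  out
}

#' Render a genome as a SNP-array sample
#'
#' Ideal values at a locus covered by \eqn{n} homologs of which \eqn{k}
#' carry the B allele are BAF \eqn{k/n} and LRR
#' \eqn{a \log_2(n/2)} (with attenuation \eqn{a}); observed values add
#' Gaussian noise, BAF clipped to \[0, 1\]. The genotype call is taken from
#' the true allele multiset (all A -> AA, all B -> BB, mixed -> AB).
#' Mitochondrial loci are rendered from the maternal MT haplotype (BAF 0
#' or 1, LRR centred on 0). Y-chromosome loci in a conceptus without a Y
#' are rendered as no-calls with LRR around -3, mimicking hemizygous-array
#' background.
#'
#' @param genome a \code{conceptus_genome}.
#' @param noise a [noise_model()].
#' @param seed optional integer seed.
#' @param sample_id identifier written into the sample table.
#' @return A \code{snp_sample} data frame (one row per panel locus) with
#'   columns \code{sample_id}, \code{locus_id}, \code{chromosome},
#'   \code{position}, \code{gtype}, \code{baf}, \code{lrr}.
#' @export
render_array <- function(genome, noise = noise_model(), seed = NULL,
                         sample_id = "SAMPLE") {
  stopifnot(inherits(genome, "conceptus_genome"),
            inherits(noise, "noise_model"))
  panel <- genome$panel
  .with_seed(seed, function() {
    n <- nrow(panel)
    baf_true <- rep(NA_real_, n)
    lrr_true <- rep(NA_real_, n)
    gtype <- rep(NA_character_, n)
    absent <- rep(FALSE, n)
    for (chrom in unique(panel$chromosome)) {
      idx <- which(panel$chromosome == chrom)
      if (chrom == "MT") {
        b <- genome$mt
        baf_true[idx] <- as.numeric(b)
        gtype[idx] <- ifelse(b, "BB", "AA")
        lrr_true[idx] <- 0
      } else {
        ch <- genome$chromosomes[[chrom]]
        if (is.null(ch) || ncol(ch$alleles) == 0) {
          absent[idx] <- TRUE
          lrr_true[idx] <- -3
        } else {
          m <- ncol(ch$alleles)
          k <- rowSums(ch$alleles)
          baf_true[idx] <- k / m
          gtype[idx] <- ifelse(k == 0, "AA", ifelse(k == m, "BB", "AB"))
          lrr_true[idx] <- noise$lrr_attenuation * log2(m / 2)
        }
      }
    }
    baf <- pmin(1, pmax(0, baf_true + stats::rnorm(n, 0, noise$baf_sd)))
    lrr <- lrr_true + stats::rnorm(n, 0, noise$lrr_sd)
    miss <- stats::runif(n) < noise$missing_rate
    gtype[miss | absent] <- NA_character_
    baf[miss | absent] <- NA_real_
    lrr[miss & !absent] <- NA_real_
    .new_snp_sample(sample_id, panel, gtype, baf, lrr)
  })
}

.new_str_profile <- function(sample_id, alleles) {
  structure(list(sample_id = sample_id, alleles = alleles),
            class = "str_profile")
}

#' STR profile of a simulated conceptus
#'
#' Collapses the STR alleles carried by the base gametes of the conceptus
#' into the set of distinct alleles observed per locus, plus the sex-marker
#' alleles implied by the sex constitution. STR loci are modelled as
#' unlinked whole-genome markers: chromosome-specific extra homologs do
#' not add STR alleles.
#'
#' @param genome a \code{conceptus_genome}.
#' @param sample_id identifier for the profile.
#' @return Object of class \code{str_profile}: a named list of sorted
#'   character allele vectors per locus.
#' @export
render_str <- function(genome, sample_id = "SAMPLE") {
  stopifnot(inherits(genome, "conceptus_genome"))
  g <- genome$str$gamete_alleles
  alleles <- lapply(rownames(g), function(loc)
    sort(unique(g[loc, ])))
  names(alleles) <- rownames(g)
  sex_letters <- sort(unique(strsplit(genome$sex, "")[[1]]))
  alleles[[STR_SEX_MARKER]] <- sex_letters
  .new_str_profile(sample_id, alleles)
}

#' STR profile of the mother
#'
#' @param parents a [simulate_parents()] result.
#' @param sample_id identifier for the profile.
#' @return Object of class \code{str_profile}.
#' @export
mother_str_profile <- function(parents, sample_id = "MOTHER") {
  stopifnot(inherits(parents, "parental_genomes"))
  m <- parents$mother_str
  alleles <- lapply(rownames(m), function(loc) sort(unique(m[loc, ])))
  names(alleles) <- rownames(m)
  alleles[[STR_SEX_MARKER]] <- "X"
  .new_str_profile(sample_id, alleles)
}

#' Simulate a cohort of mole/mother duos
#'
#' For each constitution in the cohort specification an independent
#' father/mother pair is simulated, a conceptus is constructed, and both
#' the mole villous sample and the maternal blood sample are rendered as
#' SNP-array tables and STR profiles. A single root seed is split
#' hierarchically per case and operation, so the whole cohort is
#' reproducible.
#'
#' @param cohort_spec either a list of [constitution_spec()] objects or a
#'   data frame with columns \code{id}, \code{mode}, \code{sex},
#'   \code{extra_chromosomes} (\code{"7:maternal;11:maternal"} syntax),
#'   \code{biparental_disomies} (\code{";"}-separated) and \code{outcome}.
#' @param panel a [locus_panel()].
#' @param noise a [noise_model()].
#' @param str_panel an STR panel.
#' @param genetic_map recombination map.
#' @param seed root integer seed (required).
#' @return List of cases; each case is a list with elements \code{id},
#'   \code{spec}, \code{genome} (simulation truth), \code{mole} and
#'   \code{mother} (\code{snp_sample} tables), \code{mole_str},
#'   \code{mother_str} and \code{outcome}.
#' @export
simulate_cohort <- function(cohort_spec, panel = default_locus_panel(),
                            noise = noise_model(),
                            str_panel = default_str_panel(),
                            genetic_map = default_genetic_map(),
                            seed = 1L) {
  specs <- as_constitution_specs(cohort_spec)
  lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    id <- if (!is.null(spec$id)) spec$id else sprintf("CASE%02d", i)
    parents <- simulate_parents(panel, str_panel,
                                seed = .split_seed(seed, i * 10 + 1))
    genome <- construct_conceptus(spec, parents, genetic_map,
                                  seed = .split_seed(seed, i * 10 + 2))
    mole <- render_array(genome, noise, seed = .split_seed(seed, i * 10 + 3),
                         sample_id = id)
    mother <- render_array(maternal_genome(parents), noise,
                           seed = .split_seed(seed, i * 10 + 4),
                           sample_id = paste0(id, "_PT"))
    list(
      id = id, spec = spec, genome = genome,
      mole = mole, mother = mother,
      mole_str = render_str(genome, sample_id = id),
      mother_str = mother_str_profile(parents,
                                      sample_id = paste0(id, "_PT")),
      outcome = spec$outcome
    )
  })
}

#' Coerce a cohort description to a list of constitution specs
#'
#' @param cohort_spec list of specs or a data frame (see
#'   [simulate_cohort()]).
#' @return List of \code{constitution_spec} objects.
#' @export
as_constitution_specs <- function(cohort_spec) {
  if (is.data.frame(cohort_spec)) {
    lapply(seq_len(nrow(cohort_spec)), function(i) {
      row <- cohort_spec[i, ]
      extras <- character()
      if (!is.na(row$extra_chromosomes) && nzchar(row$extra_chromosomes)) {
        parts <- strsplit(row$extra_chromosomes, ";", fixed = TRUE)[[1]]
        kv <- strsplit(parts, ":", fixed = TRUE)
        extras <- vapply(kv, `[`, "", 2)
        names(extras) <- vapply(kv, `[`, "", 1)
      }
      bipar <- character()
      if (!is.na(row$biparental_disomies) && nzchar(row$biparental_disomies))
        bipar <- strsplit(row$biparental_disomies, ";", fixed = TRUE)[[1]]
      constitution_spec(row$mode, sex = row$sex, extra_chromosomes = extras,
                        biparental_disomies = bipar, id = row$id,
                        outcome = row$outcome)
    })
  } else if (is.list(cohort_spec)) {
    stopifnot(all(vapply(cohort_spec, inherits, TRUE, "constitution_spec")))
    cohort_spec
  } else stop("unsupported cohort specification")
}

#' Reference 31-case dispermic CHM cohort constitutions
#'
#' The package's shipped default cohort: 31 androgenetic dispermic complete
#' moles with their sex constitutions, extra chromosomes (with parental
#' origin), biparental disomic chromosomes and post-molar outcomes. It
#' contains 22 euploid cases, 8 autosomal-trisomy cases (one of them a
#' double trisomy), one 47,XYY case, and three biparental disomies.
#'
#' @return Data frame suitable for [simulate_cohort()].
#' @export
chm31_cohort <- function() {
  path <- system.file("extdata", "chm31_constitutions.csv",
                      package = "molekaryo", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
}
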