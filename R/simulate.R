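## Simulation of parental genomes, gametes and molar conceptus constitutions.

#' Simulate a father/mother pair over a locus panel
#'
#' Draws parental haplotypes allele by allele: at each locus the B allele is
#' carried with probability equal to the locus's population B-allele
#' frequency, independently per haplotype. The father carries two autosomal
#' haplotypes per chromosome plus one X and one Y haplotype; the mother two
#' autosomal haplotypes, two X haplotypes and one mitochondrial haplotype.
#' STR alleles (two per parent per locus) are drawn at the same time from
#' the STR panel's population frequencies.
#'
#' @param panel a [locus_panel()].
#' @param str_panel an STR panel as from [default_str_panel()].
#' @param seed integer seed; identical seeds give identical parents.
#' @return An object of class \code{parental_genomes}: nested lists of
#'   logical allele vectors (\code{TRUE} = B allele) keyed by chromosome,
#'   plus STR allele matrices, carrying the panels used.
#' @export
simulate_parents <- function(panel, str_panel = default_str_panel(),
                             seed = NULL) {
  if (!inherits(panel, "locus_panel")) stop("'panel' must be a locus_panel")
  if (nrow(panel) == 0) stop("empty locus panel: nothing to simulate")
  .with_seed(seed, function() {
    freq_of <- function(chrom) panel$pop_b_freq[panel$chromosome == chrom]
    draw_hap <- function(p) stats::rbinom(length(p), 1, p) == 1
    draw_mat <- function(p, k) {
      m <- matrix(FALSE, length(p), k)
      for (j in seq_len(k)) m[, j] <- draw_hap(p)
      m
    }
    auto_chroms <- intersect(AUTOSOMES, unique(panel$chromosome))
    father_auto <- lapply(auto_chroms, function(ch) draw_mat(freq_of(ch), 2))
    mother_auto <- lapply(auto_chroms, function(ch) draw_mat(freq_of(ch), 2))
    names(father_auto) <- names(mother_auto) <- auto_chroms

    father <- list(auto = father_auto)
    mother <- list(auto = mother_auto)
    if ("X" %in% panel$chromosome) {
      father$X <- draw_hap(freq_of("X"))
      mother$X <- draw_mat(freq_of("X"), 2)
    }
    if ("Y" %in% panel$chromosome) father$Y <- draw_hap(freq_of("Y"))
    if ("MT" %in% panel$chromosome) mother$MT <- draw_hap(freq_of("MT"))

    draw_str <- function() {
      loci <- unique(str_panel$locus)
      m <- matrix(NA_character_, nrow = length(loci), ncol = 2,
                  dimnames = list(loci, NULL))
      for (loc in loci) {
        rows <- str_panel[str_panel$locus == loc, ]
        m[loc, ] <- sample(rows$allele, 2, replace = TRUE, prob = rows$freq)
      }
      m
    }
    out <- list(
      father = father, mother = mother,
      father_str = draw_str(), mother_str = draw_str(),
      panel = panel, str_panel = str_panel
    )
    class(out) <- "parental_genomes"
    out
  })
}

#' Simulate one gamete by meiotic recombination
#'
#' For each recombining chromosome (genetic length > 0) the number of
#' crossovers is Poisson with mean equal to the genetic length in Morgans,
#' crossover genetic positions are uniform, and the gamete alternates
#' between the two parental haplotypes at each crossover, starting from a
#' uniformly chosen haplotype. Non-recombining chromosomes (length 0) are
#' transmitted intact from a uniformly chosen haplotype (or the single
#' haplotype supplied).
#'
#' @param haplotypes named list keyed by chromosome; each element a logical
#'   matrix with one column per parental haplotype (two columns required
#'   where the genetic length is positive).
#' @param positions named list of physical positions matching
#'   \code{haplotypes} row for row.
#' @param genetic_map \code{data.frame} with columns \code{chromosome},
#'   \code{morgans}, as from [default_genetic_map()].
#' @param seed optional integer seed.
#' @return Named list of logical allele vectors, one per chromosome.
#' @export
simulate_gamete <- function(haplotypes, positions,
                            genetic_map = default_genetic_map(),
                            seed = NULL) {
  .with_seed(seed, function() {
    out <- lapply(names(haplotypes), function(chrom) {
      hap <- haplotypes[[chrom]]
      if (is.vector(hap)) hap <- matrix(hap, ncol = 1)
      morgans <- genetic_map$morgans[genetic_map$chromosome == chrom]
      if (length(morgans) == 0) morgans <- 0
      .recombine(hap, positions[[chrom]], morgans)
    })
    names(out) <- names(haplotypes)
    out
  })
}

# One meiotic product for one chromosome.
.recombine <- function(hap, pos, morgans) {
  n <- nrow(hap)
  if (morgans > 0 && ncol(hap) < 2)
    stop("recombining chromosome needs two parental haplotypes")
  start <- sample.int(ncol(hap), 1)
  if (morgans == 0) return(hap[, start])
  n_cx <- stats::rpois(1, morgans)
  if (n_cx == 0 || n < 2) return(hap[, start])
  cx <- sort(stats::runif(n_cx, 0, morgans))
  gpos <- morgans * (pos - pos[1]) / (pos[n] - pos[1])
  flips <- findInterval(gpos, cx)
  idx <- ((start - 1 + flips) %% 2) + 1
  hap[cbind(seq_len(n), idx)]
}

#' Describe a conceptus constitution
#'
#' @param mode one of \code{"monospermic_CHM"}, \code{"dispermic_CHM"},
#'   \code{"biparental_diploid"}, \code{"diandric_triploid_PHM"},
#'   \code{"digynic_triploid"}.
#' @param sex sex-chromosome constitution, e.g. \code{"XX"}, \code{"XY"},
#'   \code{"XYY"}, \code{"XXYY"} (triploid modes may use three letters).
#' @param extra_chromosomes named character vector mapping autosome labels
#'   to \code{"maternal"} or \code{"paternal"}: each entry adds one extra
#'   homolog of the stated origin (trisomy of that chromosome).
#' @param biparental_disomies character vector of autosomes on which one
#'   paternal homolog is replaced by a maternal homolog (copy number stays
#'   2, but with biparental origin). Only meaningful inside androgenetic
#'   modes.
#' @param id,outcome optional case identifier and post-molar outcome label
#'   (\code{"SR"} spontaneous remission / \code{"GTN"} neoplasia), carried
#'   through to cohort reports.
#' @return Object of class \code{constitution_spec}.
#' @export
constitution_spec <- function(mode, sex = "XX",
                              extra_chromosomes = character(),
                              biparental_disomies = character(),
                              id = NULL, outcome = NA_character_) {
  modes <- c("monospermic_CHM", "dispermic_CHM", "biparental_diploid",
             "diandric_triploid_PHM", "digynic_triploid")
  mode <- match.arg(mode, modes)
  sex_letters <- strsplit(sex, "")[[1]]
  if (!all(sex_letters %in% c("X", "Y")) || !("X" %in% sex_letters))
    stop("'sex' must be a string of X/Y letters containing at least one X")
  extra_chromosomes <- vapply(extra_chromosomes, as.character, "")
  if (length(extra_chromosomes)) {
    if (!all(names(extra_chromosomes) %in% AUTOSOMES))
      stop("extra chromosomes must name autosomes")
    if (!all(extra_chromosomes %in% c("maternal", "paternal")))
      stop("extra-chromosome origins must be 'maternal' or 'paternal'")
  }
  biparental_disomies <- as.character(biparental_disomies)
  if (length(biparental_disomies) && !all(biparental_disomies %in% AUTOSOMES))
    stop("biparental disomies must name autosomes")
  androgenetic <- mode %in% c("monospermic_CHM", "dispermic_CHM")
  if (length(biparental_disomies) && !androgenetic)
    stop("biparental disomies are only defined for androgenetic modes")
  structure(
    list(mode = mode, sex = sex, extra_chromosomes = extra_chromosomes,
         biparental_disomies = biparental_disomies, id = id,
         outcome = outcome),
    class = "constitution_spec"
  )
}

# number of eggs contributing to the base genome per mode
.n_eggs <- function(mode) {
  switch(mode,
    monospermic_CHM = 0L, dispermic_CHM = 0L,
    biparental_diploid = 1L, diandric_triploid_PHM = 1L,
    digynic_triploid = 2L
  )
}

.n_sperm <- function(mode) {
  switch(mode,
    monospermic_CHM = 1L, dispermic_CHM = 2L,
    biparental_diploid = 1L, diandric_triploid_PHM = 2L,
    digynic_triploid = 1L
  )
}

#' Build a conceptus genome from a constitution spec
#'
#' Generates the gametes the constitution requires (sperm by paternal
#' meiosis, eggs by maternal meiosis), assembles per-chromosome homolog
#' sets tagged with parental origin and source gamete, applies extra
#' chromosomes and biparental-disomy replacements, and copies the maternal
#' mitochondrial haplotype. A monospermic CHM is one sperm endoduplicated
#' (fully homozygous); a dispermic CHM is the union of two independent
#' sperm from the same father.
#'
#' @param spec a [constitution_spec()].
#' @param parents a [simulate_parents()] result.
#' @param genetic_map recombination map, see [default_genetic_map()].
#' @param seed optional integer seed.
#' @return Object of class \code{conceptus_genome}: per-chromosome lists
#'   with an allele matrix (loci x homologs), origin tags and gamete
#'   indices; the maternal MT haplotype; per-gamete STR alleles.
#' @export
construct_conceptus <- function(spec, parents,
                                genetic_map = default_genetic_map(),
                                seed = NULL) {
  stopifnot(inherits(spec, "constitution_spec"),
            inherits(parents, "parental_genomes"))
  panel <- parents$panel
  .with_seed(seed, function() {
    pos_of <- function(chrom) panel$position[panel$chromosome == chrom]
    auto_chroms <- names(parents$father$auto)
    morgans_of <- function(chrom) {
      m <- genetic_map$morgans[genetic_map$chromosome == chrom]
      if (length(m)) m else 0
    }
    sperm_auto <- function() {
      out <- lapply(auto_chroms, function(ch)
        .recombine(parents$father$auto[[ch]], pos_of(ch), morgans_of(ch)))
      names(out) <- auto_chroms
      out
    }
    egg_auto <- function() {
      out <- lapply(auto_chroms, function(ch)
        .recombine(parents$mother$auto[[ch]], pos_of(ch), morgans_of(ch)))
      names(out) <- auto_chroms
      out
    }
    egg_x <- function() .recombine(parents$mother$X, pos_of("X"),
                                   morgans_of("X"))
    maternal_homolog <- function(chrom)
      .recombine(parents$mother$auto[[chrom]], pos_of(chrom),
                 morgans_of(chrom))
    paternal_homolog <- function(chrom)
      .recombine(parents$father$auto[[chrom]], pos_of(chrom),
                 morgans_of(chrom))

    n_sperm <- .n_sperm(spec$mode)
    n_eggs <- .n_eggs(spec$mode)
    sperm <- replicate(n_sperm, sperm_auto(), simplify = FALSE)
    eggs <- replicate(n_eggs, egg_auto(), simplify = FALSE)

    # base gametes in order: sperm first, then eggs; monospermic CHM
    # endoduplicates its single sperm (gamete index repeated)
    base_haps <- c(sperm, eggs)
    base_origin <- c(rep("paternal", n_sperm), rep("maternal", n_eggs))
    base_index <- seq_along(base_haps)
    if (spec$mode == "monospermic_CHM") {
      base_haps <- c(base_haps, base_haps)
      base_origin <- c(base_origin, base_origin)
      base_index <- c(base_index, base_index)
    }

    chromosomes <- lapply(auto_chroms, function(ch) {
      alleles <- vapply(base_haps, function(g) g[[ch]],
                        logical(length(pos_of(ch))))
      if (is.vector(alleles)) alleles <- matrix(alleles, nrow = 1)
      list(alleles = alleles, origin = base_origin, gamete = base_index)
    })
    names(chromosomes) <- auto_chroms

    # sex chromosomes: eggs each contribute an X; remaining letters are
    # paternal (father has a single X and a single Y haplotype); panels
    # without sex-chromosome loci simply skip this compartment
    has_x <- !is.null(parents$father$X)
    has_y <- !is.null(parents$father$Y)
    sex_letters <- strsplit(spec$sex, "")[[1]]
    n_x <- sum(sex_letters == "X")
    n_y <- sum(sex_letters == "Y")
    n_x_mat <- n_eggs * (if (spec$mode == "monospermic_CHM") 2L else 1L)
    if (n_x < n_x_mat)
      stop("sex constitution '", spec$sex,
           "' incompatible with the number of contributing eggs")
    n_x_pat <- n_x - n_x_mat
    x_cols <- list(); x_origin <- character(); x_gamete <- integer()
    if (n_x_mat > 0 && has_x) {
      for (i in seq_len(n_eggs)) {
        xe <- egg_x()
        reps <- if (spec$mode == "monospermic_CHM") 2L else 1L
        for (r in seq_len(reps)) {
          x_cols <- c(x_cols, list(xe))
          x_origin <- c(x_origin, "maternal")
          x_gamete <- c(x_gamete, n_sperm + i)
        }
      }
    }
    sperm_cycle <- function(i) ((i - 1L) %% max(n_sperm, 1L)) + 1L
    if (n_x_pat > 0 && has_x) {
      for (i in seq_len(n_x_pat)) {
        x_cols <- c(x_cols, list(parents$father$X))
        x_origin <- c(x_origin, "paternal")
        x_gamete <- c(x_gamete, sperm_cycle(i))
      }
    }
    if (length(x_cols)) {
      chromosomes$X <- list(
        alleles = do.call(cbind, x_cols),
        origin = x_origin, gamete = x_gamete
      )
    }
    if (n_y > 0 && has_y) {
      y_cols <- replicate(n_y, parents$father$Y, simplify = FALSE)
      chromosomes$Y <- list(
        alleles = do.call(cbind, y_cols),
        origin = rep("paternal", n_y),
        gamete = vapply(seq_len(n_y), sperm_cycle, 1L)
      )
    }

    touched <- c(names(spec$extra_chromosomes), spec$biparental_disomies)
    absent <- setdiff(touched, auto_chroms)
    if (length(absent))
      stop("constitution references chromosome(s) absent from the panel: ",
           paste(absent, collapse = ", "))
    next_gamete <- length(base_haps) + 1L
    add_homolog <- function(ch, chrom, origin) {
      hap <- if (origin == "maternal") maternal_homolog(chrom)
             else paternal_homolog(chrom)
      ch$alleles <- cbind(ch$alleles, hap)
      ch$origin <- c(ch$origin, origin)
      ch$gamete <- c(ch$gamete, next_gamete)
      next_gamete <<- next_gamete + 1L
      ch
    }
    for (chrom in names(spec$extra_chromosomes)) {
      chromosomes[[chrom]] <- add_homolog(
        chromosomes[[chrom]], chrom, spec$extra_chromosomes[[chrom]])
    }
    for (chrom in spec$biparental_disomies) {
      ch <- chromosomes[[chrom]]
      drop <- which(ch$origin == "paternal")[1]
      hap <- maternal_homolog(chrom)
      ch$alleles[, drop] <- hap
      ch$origin[drop] <- "maternal"
      ch$gamete[drop] <- next_gamete
      next_gamete <<- next_gamete + 1L
      chromosomes[[chrom]] <- ch
    }

    # STR alleles: one allele per locus per base gamete, drawn from the
    # transmitting parent's two alleles (loci unlinked)
    str_loci <- rownames(parents$father_str)
    gamete_str <- matrix(NA_character_, nrow = length(str_loci),
                         ncol = length(base_haps),
                         dimnames = list(str_loci, NULL))
    gamete_origin <- base_origin
    drawn <- vector("list", max(base_index))
    for (j in seq_along(base_haps)) {
      gi <- base_index[j]
      if (is.null(drawn[[gi]])) {
        src <- if (base_origin[j] == "paternal") parents$father_str
               else parents$mother_str
        pick <- sample.int(2, length(str_loci), replace = TRUE)
        drawn[[gi]] <- src[cbind(seq_along(str_loci), pick)]
      }
      gamete_str[, j] <- drawn[[gi]]
    }

    out <- list(
      chromosomes = chromosomes,
      mt = parents$mother$MT,
      sex = spec$sex,
      spec = spec,
      panel = panel,
      str = list(gamete_alleles = gamete_str,
                 gamete_origin = gamete_origin,
                 str_panel = parents$str_panel)
    )
    class(out) <- "conceptus_genome"
    out
  })
}

#' View the mother's own genome as a renderable genome object
#'
#' Wraps the maternal haplotypes (two per autosome, two X, no Y, one MT)
#' in the same structure as a [construct_conceptus()] result so the same
#' array renderer applies to the maternal blood sample.
#'
#' @param parents a [simulate_parents()] result.
#' @return Object of class \code{conceptus_genome}.
#' @export
maternal_genome <- function(parents) {
  stopifnot(inherits(parents, "parental_genomes"))
  chromosomes <- lapply(parents$mother$auto, function(m)
    list(alleles = m, origin = c("maternal", "maternal"), gamete = c(1L, 2L)))
  if (!is.null(parents$mother$X)) {
    chromosomes$X <- list(alleles = parents$mother$X,
                          origin = c("maternal", "maternal"),
                          gamete = c(1L, 2L))
  }
  out <- list(
    chromosomes = chromosomes,
    mt = parents$mother$MT,
    sex = "XX",
    spec = NULL,
    panel = parents$panel,
    str = list(
      gamete_alleles = parents$mother_str,
      gamete_origin = c("maternal", "maternal"),
      str_panel = parents$str_panel
    )
  )
  class(out) <- "conceptus_genome"
  out
}

#' True per-chromosome copy number of a simulated genome
#'
#' @param genome a \code{conceptus_genome}.
#' @return Named integer vector over the chromosomes present.
#' @export
true_copy_number <- function(genome) {
  stopifnot(inherits(genome, "conceptus_genome"))
  vapply(genome$chromosomes, function(ch) ncol(ch$alleles), 0L)
}
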