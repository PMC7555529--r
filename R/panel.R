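## Locus panels, genetic maps and STR panels used by the simulator.

#' Chromosome labels in canonical order
#'
#' Autosomes \code{"1"}..\code{"22"}, then \code{"X"}, \code{"Y"},
#' \code{"MT"}. Used for sorting and validation throughout the package.
#' @export
CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT")

#' @rdname CHROMOSOMES
#' @export
AUTOSOMES <- as.character(1:22)

# approximate chromosome physical sizes (Mb); MT in bp handled separately
.chrom_mb <- c(
  `1` = 249, `2` = 243, `3` = 198, `4` = 191, `5` = 181, `6` = 171,
  `7` = 159, `8` = 146, `9` = 141, `10` = 136, `11` = 135, `12` = 134,
  `13` = 115, `14` = 107, `15` = 102, `16` = 90, `17` = 81, `18` = 78,
  `19` = 59, `20` = 63, `21` = 48, `22` = 51, X = 155, Y = 59
)

.chrom_order <- function(chromosome) match(as.character(chromosome), CHROMOSOMES)

#' Construct a locus panel
#'
#' A locus panel is the universe of array loci: one row per locus with its
#' chromosome, physical position and population B-allele frequency. All
#' simulated genomes and rendered samples are defined over a panel.
#'
#' @param locus_id character vector of unique locus identifiers.
#' @param chromosome chromosome label per locus (one of [CHROMOSOMES]).
#' @param position 1-based physical position (bp), strictly increasing
#'   within each chromosome.
#' @param pop_b_freq population frequency of the B allele, in (0, 1).
#' @return A \code{data.frame} of class \code{locus_panel}.
#' @export
locus_panel <- function(locus_id, chromosome, position, pop_b_freq) {
  chromosome <- as.character(chromosome)
  if (anyNA(.chrom_order(chromosome)))
    stop("unknown chromosome label in panel")
  if (anyDuplicated(locus_id))
    stop("locus_id values must be unique")
  if (any(pop_b_freq <= 0 | pop_b_freq >= 1))
    stop("pop_b_freq must lie strictly inside (0, 1)")
  panel <- data.frame(
    locus_id = as.character(locus_id),
    chromosome = chromosome,
    position = as.integer(position),
    pop_b_freq = as.numeric(pop_b_freq),
    stringsAsFactors = FALSE
  )
  panel <- panel[order(.chrom_order(panel$chromosome), panel$position), ]
  rownames(panel) <- NULL
  for (chrom in unique(panel$chromosome)) {
    pos <- panel$position[panel$chromosome == chrom]
    if (anyDuplicated(pos))
      stop("duplicate positions on chromosome ", chrom)
  }
  class(panel) <- c("locus_panel", "data.frame")
  panel
}

#' Default simulation locus panel
#'
#' Exome-array-like panel: autosomal loci distributed proportionally to
#' physical chromosome size, a block of X and Y loci, and 208 mitochondrial
#' loci. Population B-allele frequencies are drawn uniformly so that most
#' loci are informative.
#'
#' @param n_autosomal,n_x,n_y,n_mt locus counts per compartment.
#' @param freq_range range of the uniform population B-allele frequency.
#' @param seed integer seed; the panel itself is part of the simulated
#'   study conditions and is reproducible.
#' @return A [locus_panel()].
#' @export
default_locus_panel <- function(n_autosomal = 20000, n_x = 800, n_y = 100,
                                n_mt = 208, freq_range = c(0.05, 0.95),
                                seed = 1L) {
  .with_seed(seed, function() {
    sizes <- .chrom_mb[AUTOSOMES]
    n_per <- stats::setNames(pmax(2L, round(n_autosomal * sizes / sum(sizes))),
                             names(sizes))
    counts <- c(n_per, X = n_x, Y = n_y)
    pieces <- lapply(names(counts), function(chrom) {
      n <- counts[[chrom]]
      span <- .chrom_mb[[chrom]] * 1e6
      data.frame(
        locus_id = sprintf("snp_%s_%05d", chrom, seq_len(n)),
        chromosome = chrom,
        position = sort(sample.int(span, n)),
        pop_b_freq = stats::runif(n, freq_range[1], freq_range[2]),
        stringsAsFactors = FALSE
      )
    })
    mt <- data.frame(
      locus_id = sprintf("mt_%04d", seq_len(n_mt)),
      chromosome = "MT",
      position = sort(sample.int(16569L, n_mt)),
      pop_b_freq = stats::runif(n_mt, freq_range[1], freq_range[2]),
      stringsAsFactors = FALSE
    )
    all <- do.call(rbind, c(pieces, list(mt)))
    locus_panel(all$locus_id, all$chromosome, all$position, all$pop_b_freq)
  })
}

#' Default genetic map
#'
#' Genetic lengths in Morgans per chromosome, scaled linearly with physical
#' size between 1.0 and 2.8 Morgans for recombining chromosomes (autosomes
#' and X). Y and MT do not recombine (length 0). Physical-to-genetic
#' mapping along a chromosome is linear.
#'
#' @param min_morgans,max_morgans genetic length assigned to the smallest
#'   and largest recombining chromosome.
#' @return \code{data.frame} with columns \code{chromosome}, \code{morgans}.
#' @export
default_genetic_map <- function(min_morgans = 1.0, max_morgans = 2.8) {
  recomb <- c(AUTOSOMES, "X")
  mb <- .chrom_mb[recomb]
  morgans <- min_morgans +
    (max_morgans - min_morgans) * (mb - min(mb)) / (max(mb) - min(mb))
  data.frame(
    chromosome = c(recomb, "Y", "MT"),
    morgans = c(as.numeric(morgans), 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Default STR panel
#'
#' A 15-locus forensic-style autosomal STR panel plus a sex marker
#' (\code{"AMEL"}, alleles X/Y). Each polymorphic locus carries between 6
#' and 10 integer allele designations at uniform population frequencies.
#'
#' @param n_loci number of polymorphic loci.
#' @param allele_counts range of the per-locus allele count.
#' @param seed integer seed.
#' @return \code{data.frame} with columns \code{locus}, \code{allele},
#'   \code{freq}, of class \code{str_panel}. The sex marker is not listed:
#'   its alleles follow the simulated sex constitution.
#' @export
default_str_panel <- function(n_loci = 15, allele_counts = c(6L, 10L),
                              seed = 1L) {
  .with_seed(seed, function() {
    rows <- lapply(seq_len(n_loci), function(i) {
      k <- sample(seq(allele_counts[1], allele_counts[2]), 1)
      alleles <- seq(6L, length.out = k)
      data.frame(
        locus = sprintf("STR%02d", i),
        allele = as.character(alleles),
        freq = rep(1 / k, k),
        stringsAsFactors = FALSE
      )
    })
    panel <- do.call(rbind, rows)
    class(panel) <- c("str_panel", "data.frame")
    panel
  })
}

#' Name of the sex marker locus in STR profiles
#' @export
STR_SEX_MARKER <- "AMEL"
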