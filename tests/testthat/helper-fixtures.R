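# Shared fixtures: panels and duos are built in code, never stored.

# Small three-autosome panel for unit tests that do not need all 22
# chromosomes. Dense enough for band profiling and selected-BAF calling.
test_panel <- function(n_per = 400, chroms = c("1", "2", "21"),
                       n_x = 150, n_y = 60, n_mt = 40, seed = 42) {
  withr::with_seed(seed, {
    mk <- function(ch, n, span) data.frame(
      locus_id = sprintf("t_%s_%04d", ch, seq_len(n)),
      chromosome = ch,
      position = sort(sample.int(span, n)),
      pop_b_freq = runif(n, 0.05, 0.95),
      stringsAsFactors = FALSE
    )
    rows <- do.call(rbind, c(
      lapply(chroms, mk, n = n_per, span = 5e7),
      list(mk("X", n_x, 5e7), mk("Y", n_y, 2e7), mk("MT", n_mt, 16569))
    ))
    locus_panel(rows$locus_id, rows$chromosome, rows$position,
                rows$pop_b_freq)
  })
}

# Full default panel, built once per test run.
full_panel <- default_locus_panel()

no_noise <- noise_model(baf_sd = 0, lrr_sd = 0, missing_rate = 0)

# Simulate a single mole/mother duo under one spec.
make_duo <- function(spec, panel = test_panel(), noise = noise_model(),
                     seed = 1) {
  parents <- simulate_parents(panel, seed = seed)
  genome <- construct_conceptus(spec, parents, seed = seed + 1)
  list(
    parents = parents, genome = genome,
    mole = render_array(genome, noise, seed = seed + 2, sample_id = "MOLE"),
    mother = render_array(maternal_genome(parents), noise,
                          seed = seed + 3, sample_id = "MOTHER")
  )
}

# Hand-build an STR profile from a named list of allele vectors.
make_str_profile <- function(alleles, sample_id = "S") {
  molekaryo:::.new_str_profile(sample_id,
                               lapply(alleles, as.character))
}

# Hand-build a minimal snp_sample table.
make_snp_sample <- function(sample_id, locus_id, chromosome, position,
                            gtype, baf, lrr = 0) {
  out <- data.frame(sample_id = sample_id, locus_id = locus_id,
                    chromosome = as.character(chromosome),
                    position = as.integer(position), gtype = gtype,
                    baf = baf, lrr = lrr, stringsAsFactors = FALSE)
  class(out) <- c("snp_sample", "data.frame")
  out
}

# Per-case truth calls derived straight from a cohort constitution table
# (no simulation): used to test reporting arithmetic.
truth_case_calls <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    extras <- character()
    if (nzchar(row$extra_chromosomes)) {
      kv <- strsplit(strsplit(row$extra_chromosomes, ";")[[1]], ":")
      extras <- vapply(kv, `[`, "", 2)
      names(extras) <- vapply(kv, `[`, "", 1)
    }
    if (row$sex == "XYY") extras[["Y"]] <- "paternal"
    bipar <- if (nzchar(row$biparental_disomies))
      strsplit(row$biparental_disomies, ";")[[1]] else character()
    list(
      id = row$id, karyotype = NULL,
      extra_origins = extras, biparental_disomies = bipar,
      aneuploid = length(extras) > 0 || !(row$sex %in% c("XX", "XY")),
      maternal_contribution = any(extras == "maternal") || length(bipar) > 0,
      outcome = row$outcome
    )
  })
}
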