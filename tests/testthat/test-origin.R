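# Selected-BAF locus selection, top-band retention, origin and MT identity.

test_that("selection keeps exactly the maternal-AA loci", {
  panel <- test_panel()
  duo <- make_duo(constitution_spec("dispermic_CHM", sex = "XX"),
                  panel, noise_model(missing_rate = 0), seed = 3)
  sel <- select_loci_maternal_AA(duo$mole, duo$mother)
  mat_gt <- duo$mother$gtype[match(sel$locus_id, duo$mother$locus_id)]
  expect_true(all(mat_gt == "AA"))
  aa_loci <- duo$mother$locus_id[!is.na(duo$mother$gtype) &
                                   duo$mother$gtype == "AA"]
  expect_setequal(sel$locus_id, aa_loci)

  # mother all-BB leaves nothing selected
  bb_mother <- duo$mother
  bb_mother$gtype <- "BB"
  expect_equal(nrow(select_loci_maternal_AA(duo$mole, bb_mother)), 0)

  # a duo typed on essentially different loci is refused
  off <- duo$mother
  off$locus_id <- paste0("other_", off$locus_id)
  expect_error(select_loci_maternal_AA(duo$mole, off), "share")
})

test_that("selected-locus counts follow the binomial expectation", {
  n <- 10000
  p <- withr::with_seed(5, runif(n, 0.05, 0.95))
  panel <- locus_panel(sprintf("l%05d", 1:n), rep("1", n), seq_len(n), p)
  duo <- make_duo(constitution_spec("dispermic_CHM", sex = "XX"),
                  panel, noise_model(missing_rate = 0), seed = 6)
  sel <- select_loci_maternal_AA(duo$mole, duo$mother)
  expected <- sum((1 - p)^2)
  sd_count <- sqrt(sum((1 - p)^2 * (1 - (1 - p)^2)))
  expect_lt(abs(nrow(sel) - expected), 3.1 * sd_count)  # ~99% interval
})

test_that("retention statistic self-calibrates on independent homologs", {
  # disomy whose two homologs are independent population draws matches
  # the analytic all-paternal expectation (statistic ~ 1)
  n <- 8000
  p <- withr::with_seed(7, runif(n, 0.05, 0.95))
  panel <- locus_panel(sprintf("l%05d", 1:n), rep("1", n), seq_len(n), p)
  parents <- simulate_parents(panel, seed = 8)
  genome <- construct_conceptus(
    constitution_spec("biparental_diploid", sex = "XX"), parents, seed = 9)
  # relabel: treat the mother-father pair of homologs as "paternal" and
  # select against an unrelated second mother
  other <- simulate_parents(panel, seed = 10)
  mole <- render_array(genome, no_noise, sample_id = "M")
  mother <- render_array(maternal_genome(other), no_noise, sample_id = "P")
  sel <- select_loci_maternal_AA(mole, mother)
  ret <- top_band_retention(sel, "1", panel, copy_number = 2)
  expect_true(ret$determined)
  expect_lt(abs(ret$statistic - 1), 0.15)

  # identity-by-descent between two sperm of one father lifts the
  # statistic above the independence baseline, never below
  duo <- make_duo(constitution_spec("dispermic_CHM", sex = "XX"),
                  panel, no_noise, seed = 11)
  sel2 <- select_loci_maternal_AA(duo$mole, duo$mother)
  ret2 <- top_band_retention(sel2, "1", panel, copy_number = 2)
  expect_gt(ret2$statistic, 0.9)
})

test_that("maternal homologs structurally zero the top band", {
  panel <- test_panel()
  duo <- make_duo(
    constitution_spec("dispermic_CHM", sex = "XY",
                      extra_chromosomes = c(`2` = "maternal"),
                      biparental_disomies = "21"),
    panel, no_noise, seed = 13)
  sel <- select_loci_maternal_AA(duo$mole, duo$mother)
  for (chrom in c("2", "21")) {
    n <- true_copy_number(duo$genome)[[chrom]]
    ret <- top_band_retention(sel, chrom, panel, copy_number = n)
    expect_identical(ret$numerator, 0)
    expect_identical(ret$statistic, 0)
  }
  # the all-paternal chromosome retains its band
  ret1 <- top_band_retention(sel, "1", panel, copy_number = 2)
  expect_gt(ret1$numerator, 0)

  # sparse chromosomes yield undetermined, not forced, statistics
  thin <- top_band_retention(sel, "1", panel, copy_number = 2,
                             min_selected = 10000)
  expect_false(thin$determined)
  expect_match(thin$reason, "selected loci")
})

test_that("origin calls recover maternal and paternal extras and disomies", {
  panel <- test_panel()
  cases <- list(
    list(extras = c(`2` = "maternal"), bipar = character()),
    list(extras = c(`2` = "paternal"), bipar = character()),
    list(extras = character(), bipar = "2")
  )
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    duo <- make_duo(
      constitution_spec("dispermic_CHM", sex = "XY",
                        extra_chromosomes = cs$extras,
                        biparental_disomies = cs$bipar),
      panel, noise_model(), seed = 400 + i)
    cc <- call_copy_number(duo$mole, "2")
    oc <- call_origin(duo$mole, duo$mother, cc, panel)
    if (length(cs$extras)) {
      expect_equal(oc$extra_origin, unname(cs$extras))
      expect_false(oc$biparental_disomy)
    } else {
      expect_equal(oc$extra_origin, "n/a")
      expect_true(oc$biparental_disomy)
      expect_true(oc$maternal_contribution)
    }
  }
  amb <- structure(list(chromosome = "1", copy_number = NA_integer_,
                        ambiguous = TRUE, reason = "x"),
                   class = "chromosome_call")
  duo <- make_duo(constitution_spec("dispermic_CHM", sex = "XY"),
                  panel, noise_model(), seed = 421)
  expect_error(call_origin(duo$mole, duo$mother, amb, panel), "ambiguous")
})

test_that("maternal-BB mirror reaches the same contribution calls", {
  panel <- test_panel()
  duo <- make_duo(
    constitution_spec("dispermic_CHM", sex = "XY",
                      extra_chromosomes = c(`2` = "maternal")),
    panel, no_noise, seed = 17)
  sel_bb <- select_loci_maternal_BB(duo$mole, duo$mother)
  mat_gt <- duo$mother$gtype[match(sel_bb$locus_id, duo$mother$locus_id)]
  expect_true(all(mat_gt == "BB"))
  # maternal homolog: bottom band lost in the mirror too
  ret2 <- top_band_retention(sel_bb, "2", panel, copy_number = 3)
  expect_identical(ret2$numerator, 0)
  # all-paternal chromosome: bottom band retained
  ret1 <- top_band_retention(sel_bb, "1", panel, copy_number = 2)
  expect_gt(ret1$statistic, 0.25)
})

test_that("mitochondrial identity flags swaps and ignores uninformative loci", {
  panel <- test_panel()
  fam1 <- make_duo(constitution_spec("dispermic_CHM", sex = "XX"),
                   panel, no_noise, seed = 19)
  fam2 <- make_duo(constitution_spec("dispermic_CHM", sex = "XX"),
                   panel, no_noise, seed = 23)
  rep <- mito_identity(list(fam1$mole, fam1$mother,
                            fam2$mole, fam2$mother))
  expect_gt(rep$n_informative, 0)
  expect_true(rep$identity["MOLE", "MOTHER"])
  # same sample IDs across families; rely on positional names
  ids <- colnames(rep$identity)
  expect_true(rep$identity[1, 2] && rep$identity[3, 4])
  expect_false(rep$identity[1, 4])  # mole of family 1 vs mother of family 2
  expect_false(rep$identity[3, 2])

  solo <- mito_identity(list(fam1$mole))
  expect_equal(solo$n_informative, 0)

  no_mt <- make_snp_sample("S", "a", "1", 1L, "AA", 0)
  expect_error(mito_identity(list(no_mt)), "MT")
})
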