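# Parental genomes, gametes, conceptus construction and array rendering.

test_that("parental alleles follow population frequencies and seeds", {
  n <- 10000
  panel <- locus_panel(sprintf("l%05d", 1:n), rep("1", n), seq_len(n),
                       rep(0.5, n))
  parents <- simulate_parents(panel, seed = 5)
  het <- xor(parents$father$auto[["1"]][, 1], parents$father$auto[["1"]][, 2])
  # heterozygosity 2p(1-p) = 0.5; binomial 3-SE tolerance
  expect_lt(abs(mean(het) - 0.5), 3 * sqrt(0.25 / n))

  again <- simulate_parents(panel, seed = 5)
  expect_identical(parents$father, again$father)
  expect_identical(parents$mother, again$mother)
  expect_identical(parents$mother_str, again$mother_str)

  # near-degenerate frequency pushes alleles to A
  low <- locus_panel(sprintf("q%03d", 1:200), rep("1", 200), 1:200,
                     rep(1e-6, 200))
  p2 <- simulate_parents(low, seed = 1)
  expect_false(any(p2$father$auto[["1"]]))

  expect_error(simulate_parents(
    structure(panel[0, ], class = c("locus_panel", "data.frame"))),
    "empty")
})

test_that("gamete crossover counts follow the Poisson recombination model", {
  n <- 10000
  pos <- list(`1` = seq_len(n))
  # distinguishable haplotypes: hap1 all A, hap2 all B
  haps <- list(`1` = cbind(rep(FALSE, n), rep(TRUE, n)))
  map1 <- data.frame(chromosome = "1", morgans = 1)

  # genetic length 0: intact transmission of one haplotype
  map0 <- data.frame(chromosome = "1", morgans = 0)
  g <- simulate_gamete(haps, pos, map0, seed = 3)
  expect_true(all(g[["1"]]) || !any(g[["1"]]))

  # 1-Morgan chromosome: mean observable switch count = 1
  n_meioses <- 3000
  switches <- withr::with_seed(11, vapply(seq_len(n_meioses), function(i) {
    g <- simulate_gamete(haps, pos, map1)[["1"]]
    sum(diff(g) != 0)
  }, 0))
  expect_lt(abs(mean(switches) - 1), 3 * sqrt(1 / n_meioses))

  # two independent sperm share a paternal homolog at half their loci
  share <- withr::with_seed(13, vapply(1:200, function(i) {
    s1 <- simulate_gamete(haps, pos, map1)[["1"]]
    s2 <- simulate_gamete(haps, pos, map1)[["1"]]
    mean(s1 == s2)
  }, 0))
  expect_lt(abs(mean(share) - 0.5), 0.03)

  expect_error(
    simulate_gamete(list(`1` = matrix(FALSE, n, 1)), pos, map1),
    "two parental haplotypes")
})

test_that("conceptus construction realises the requested constitution", {
  panel <- test_panel()
  parents <- simulate_parents(panel, seed = 21)

  mono <- construct_conceptus(
    constitution_spec("monospermic_CHM", sex = "XX"), parents, seed = 22)
  for (ch in mono$chromosomes) {
    k <- rowSums(ch$alleles)
    expect_true(all(k %in% c(0, ncol(ch$alleles))))
  }

  # double maternal trisomy plus a biparental disomy (mapped onto the
  # test panel's chromosomes)
  dup <- construct_conceptus(
    constitution_spec("dispermic_CHM", sex = "XX",
                      extra_chromosomes = c(`1` = "maternal",
                                            `21` = "maternal"),
                      biparental_disomies = "2"),
    parents, seed = 23)
  cn <- true_copy_number(dup)
  expect_equal(unname(cn[c("1", "21", "2")]), c(3L, 3L, 2L))
  expect_equal(sum(dup$chromosomes[["1"]]$origin == "maternal"), 1L)
  expect_equal(sum(dup$chromosomes[["21"]]$origin == "maternal"), 1L)
  expect_equal(sum(dup$chromosomes[["2"]]$origin == "maternal"), 1L)

  bip <- construct_conceptus(
    constitution_spec("biparental_diploid", sex = "XY"), parents, seed = 24)
  for (ch in names(bip$chromosomes)) {
    if (!ch %in% AUTOSOMES) next
    expect_setequal(bip$chromosomes[[ch]]$origin, c("maternal", "paternal"))
  }

  # MT haplotype is the mother's in every mode
  expect_identical(mono$mt, parents$mother$MT)
  expect_identical(bip$mt, parents$mother$MT)

  expect_error(constitution_spec("biparental_diploid",
                                 biparental_disomies = "4"),
               "androgenetic")
  expect_error(constitution_spec("dispermic_CHM",
                                 extra_chromosomes = c(X = "maternal")),
               "autosomes")
})

test_that("noise-free rendering reproduces the ideal BAF/LRR geometry", {
  panel <- test_panel()
  duo <- make_duo(
    constitution_spec("dispermic_CHM", sex = "XY",
                      extra_chromosomes = c(`2` = "maternal")),
    panel, no_noise, seed = 31)
  mole <- duo$mole

  di <- mole[mole$chromosome == "1", ]
  expect_true(all(di$baf %in% c(0, 0.5, 1)))
  expect_true(all(di$lrr == 0))
  expect_identical(di$gtype[di$baf == 0.5], rep("AB", sum(di$baf == 0.5)))

  tri <- mole[mole$chromosome == "2", ]
  expect_true(all(tri$baf %in% c(0, 1/3, 2/3, 1)))
  expect_equal(unique(tri$lrr), log2(1.5))

  # attenuation compresses LRR multiplicatively
  att <- render_array(duo$genome,
                      noise_model(baf_sd = 0, lrr_sd = 0,
                                  lrr_attenuation = 0.6, missing_rate = 0),
                      sample_id = "ATT")
  expect_equal(unique(att$lrr[att$chromosome == "2"]), 0.6 * log2(1.5))

  # hemizygous male X, single Y, MT copied from the mother
  expect_true(all(mole$baf[mole$chromosome == "X"] %in% c(0, 1)))
  expect_equal(unique(mole$lrr[mole$chromosome == "X"]), -1)
  mt_mole <- mole$gtype[mole$chromosome == "MT"]
  mt_mother <- duo$mother$gtype[duo$mother$chromosome == "MT"]
  expect_identical(mt_mole, mt_mother)

  # Y loci in an XX conceptus are no-calls with background LRR
  xx <- make_duo(constitution_spec("dispermic_CHM", sex = "XX"),
                 panel, no_noise, seed = 35)
  y <- xx$mole[xx$mole$chromosome == "Y", ]
  expect_true(all(is.na(y$gtype)))
  expect_true(all(abs(y$lrr + 3) < 1e-9))
})

test_that("BAF noise has the configured spread and seeds fix the render", {
  n <- 10000
  panel <- locus_panel(sprintf("l%05d", 1:n), rep("1", n), seq_len(n),
                       rep(0.5, n))
  duo <- make_duo(constitution_spec("dispermic_CHM", sex = "XX"),
                  panel, noise_model(missing_rate = 0), seed = 41)
  het <- duo$mole$baf[duo$mole$gtype == "AB" & !is.na(duo$mole$gtype)]
  expect_gt(length(het), 2000)
  expect_lt(abs(sd(het) - 0.03), 0.002)

  again <- render_array(duo$genome, noise_model(missing_rate = 0),
                        seed = 43, sample_id = "MOLE")
  expect_identical(duo$mole, again)
})

test_that("dispermic moles show segmental homozygosity at father-het loci", {
  panel <- test_panel()
  duo <- make_duo(constitution_spec("dispermic_CHM", sex = "XX"),
                  panel, no_noise, seed = 51)
  states <- unlist(lapply(c("1", "2", "21"), function(chrom) {
    f <- duo$parents$father$auto[[chrom]]
    het <- xor(f[, 1], f[, 2])
    k <- rowSums(duo$genome$chromosomes[[chrom]]$alleles)
    state <- (k == 1)[het]  # mole het iff the two sperm disagree here
    expect_lt(sum(diff(state) != 0), 15)  # few crossover-driven switches
    state
  }))
  expect_true(any(states) && !all(states))  # both run types occur
})

test_that("STR rendering reflects gamete composition", {
  panel <- test_panel()
  parents <- simulate_parents(panel, seed = 61)

  mono <- render_str(construct_conceptus(
    constitution_spec("monospermic_CHM", sex = "XX"), parents, seed = 62))
  polym <- setdiff(names(mono$alleles), STR_SEX_MARKER)
  expect_true(all(lengths(mono$alleles[polym]) == 1))

  disp <- render_str(construct_conceptus(
    constitution_spec("dispermic_CHM", sex = "XY"), parents, seed = 63))
  for (loc in polym) {
    expect_true(all(disp$alleles[[loc]] %in% parents$father_str[loc, ]))
    expect_lte(length(disp$alleles[[loc]]), 2)
  }
  expect_setequal(disp$alleles[[STR_SEX_MARKER]], c("X", "Y"))

  bip <- render_str(construct_conceptus(
    constitution_spec("biparental_diploid", sex = "XX"), parents, seed = 64))
  mom <- mother_str_profile(parents)
  for (loc in polym)
    expect_gte(length(intersect(bip$alleles[[loc]], mom$alleles[[loc]])), 1)
})

test_that("cohort simulation is seed-deterministic and spec-faithful", {
  tab <- chm31_cohort()
  expect_equal(nrow(tab), 31)
  n_aneu <- sum(nzchar(tab$extra_chromosomes) | !(tab$sex %in% c("XX", "XY")))
  expect_equal(n_aneu, 9)

  panel <- test_panel()
  small <- tab[c(1, 4, 5), ]  # cases whose constitutions fit the test panel
  c1 <- simulate_cohort(small, panel = panel, seed = 99)
  c2 <- simulate_cohort(small, panel = panel, seed = 99)
  expect_identical(lapply(c1, `[[`, "mole"), lapply(c2, `[[`, "mole"))
  expect_identical(lapply(c1, `[[`, "mole_str"),
                   lapply(c2, `[[`, "mole_str"))
  expect_equal(length(simulate_cohort(tab[0, ], panel = panel, seed = 1)), 0)
})

test_that("maternal homologs cap the true BAF below 1", {
  panel <- test_panel()
  duo <- make_duo(
    constitution_spec("dispermic_CHM", sex = "XX",
                      extra_chromosomes = c(`2` = "maternal"),
                      biparental_disomies = "21"),
    panel, no_noise, seed = 71)
  for (chrom in c("2", "21")) {
    ch <- duo$genome$chromosomes[[chrom]]
    j <- which(ch$origin == "maternal")[1]
    mother_a <- !ch$alleles[, j]
    n <- ncol(ch$alleles)
    baf <- duo$mole$baf[duo$mole$chromosome == chrom]
    expect_true(all(baf[mother_a] <= (n - 1) / n))
  }
})
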