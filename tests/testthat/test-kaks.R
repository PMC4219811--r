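test_that("site counting matches hand enumeration for canonical codons", {
  expect_equal(count_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(count_sites("ATG"), c(s = 0, n = 3))   # Met: no silent change
  # every sense codon splits its 3 positions exactly into s + n
  for (cd in oracle_sense_codons) {
    cs <- count_sites(cd)
    expect_equal(unname(sum(cs)), 3)
  }
  expect_error(count_sites("TAA"), "sense codon")
})

test_that("kappa and frequency weighting shift the site split as expected", {
  # raising kappa favours the synonymous third-position transition of Phe
  expect_gt(count_sites("TTT", kappa = 4)[["s"]], count_sites("TTT")[["s"]])
  # uniform frequencies reproduce the unweighted split
  expect_equal(count_sites("TTT", codon_frequencies = uniform_codon_frequencies()),
               count_sites("TTT"), tolerance = 1e-12)
})

test_that("pathway counting averages over stop-free orderings", {
  expect_equal(count_differences("TTT", "TTC")[c("sd", "nd", "transitions")],
               c(sd = 1, nd = 0, transitions = 1))
  expect_equal(count_differences("ATG", "ATG")[["sd"]], 0)
  d <- count_differences("TTT", "GTA")
  expect_equal(d[["sd"]], 0.5)
  expect_equal(d[["nd"]], 1.5)
  expect_equal(d[["sd"]] + d[["nd"]], 2)  # two differing positions
  # ts/tv cross-classification is a refinement of the marginals
  expect_equal(d[["sd_ts"]] + d[["sd_tv"]], d[["sd"]])
  expect_equal(d[["nd_ts"]] + d[["nd_tv"]], d[["nd"]])
})

test_that("distance corrections follow the closed forms", {
  expect_equal(correct_distance(0, "JC"), 0)
  expect_equal(correct_distance(0.1, "JC"), -0.75 * log(1 - 0.4 / 3),
               tolerance = 1e-12)
  expect_gt(correct_distance(0.2, "JC"), 0.2)
  # K80 collapses to JC under uniform rates, where transitions are one
  # third of all changes (one transition vs two transversion targets)
  p <- 0.12
  expect_equal(correct_distance(NULL, "K80", p_transition = p / 3,
                                p_transversion = 2 * p / 3),
               correct_distance(p, "JC"), tolerance = 1e-12)
  expect_error(correct_distance(0.8, "JC"), "saturation")
  expect_error(correct_distance(NULL, "K80", p_transition = 0.45,
                                p_transversion = 0.2), "saturation")
})

test_that("NG86 estimator handles identity, symmetry and saturation", {
  a <- random_cds(60, seed = 11)
  id <- kaks(a, a, method = "ng86")
  expect_equal(id$Ka, 0)
  expect_equal(id$Ks, 0)
  expect_true(is.na(id$omega))
  b <- random_cds(60, seed = 12)
  ab <- kaks(a, b, method = "ng86")
  ba <- kaks(b, a, method = "ng86")
  expect_equal(coef(ab), coef(ba))
  expect_equal(ab$S_sites + ab$N_sites, 3 * ab$n_codons, tolerance = 1e-6)
  # single synonymous column: ps = 1/(1/3) = 3, beyond the JC domain
  sat <- estimate_kaks_ng86(codon_alignment("TTT", "TTC"))
  expect_true("saturated" %in% sat$flags)
  expect_true(is.na(sat$Ks))
})

test_that("kappa estimation falls back and caps as documented", {
  # identical sequences: no third-position divergence, kappa = 1
  a <- random_cds(200, seed = 3)
  expect_equal(estimate_kappa(codon_alignment(a, a)), 1)
  # fewer than 10 four-fold sites: fallback with a warning
  short <- strrep("ATGTTT", 8)   # Met/Phe only, no four-fold family
  expect_warning(k <- estimate_kappa(codon_alignment(short, short)),
                 "fewer than 10")
  expect_equal(k, 1)
  # transitions-only divergence at four-fold sites hits the cap
  g1 <- strrep("GGA", 30)
  g2 <- paste(rep(c("GGA", "GGG"), 15), collapse = "")  # A<->G third pos
  expect_warning(k2 <- estimate_kappa(codon_alignment(g1, g2)),
                 "capped")
  expect_equal(k2, 20)
})

test_that("YN estimator reduces to NG86 components under kappa=1/uniform", {
  set.seed(21)
  anc <- sample(oracle_sense_codons, 600, replace = TRUE)
  ev <- evolve_codon_sequence(anc, 0.1, omega = 0.5, kappa = 1, seed = 22)
  aln <- codon_alignment(anc, ev)
  yn <- estimate_kaks_yn(aln, kappa = 1,
                         codon_frequencies = uniform_codon_frequencies())
  ng <- estimate_kaks_ng86(aln)
  # identical counting layer...
  expect_equal(yn$S_sites, ng$S_sites, tolerance = 1e-9)
  expect_equal(yn$Sd, ng$Sd, tolerance = 1e-9)
  expect_equal(yn$Nd, ng$Nd, tolerance = 1e-9)
  # ...and the YN distances equal K80 applied to the NG86 proportions
  expect_equal(yn$Ks,
               correct_distance(NULL, "K80",
                                p_transition = ng$Sd_ts / ng$S_sites,
                                p_transversion = ng$Sd_tv / ng$S_sites),
               tolerance = 1e-9)
  expect_equal(yn$Ka,
               correct_distance(NULL, "K80",
                                p_transition = ng$Nd_ts / ng$N_sites,
                                p_transversion = ng$Nd_tv / ng$N_sites),
               tolerance = 1e-9)
})

test_that("YN estimator is symmetric and conserves sites", {
  set.seed(31)
  anc <- sample(oracle_sense_codons, 500, replace = TRUE)
  ev <- evolve_codon_sequence(anc, 0.15, omega = 0.8, kappa = 3, seed = 32)
  ab <- kaks(codon_alignment(anc, ev), method = "yn")
  ba <- kaks(codon_alignment(ev, anc), method = "yn")
  expect_equal(coef(ab), coef(ba), tolerance = 1e-12)
  expect_equal(ab$S_sites + ab$N_sites, 3 * ab$n_codons, tolerance = 1e-6)
  expect_equal(ab$omega, ab$Ka / ab$Ks)
})

test_that("Ks is monotone in branch length on simulated pairs", {
  set.seed(41)
  bls <- c(0.02, 0.05, 0.1, 0.2)
  Q <- codon_rate_matrix(0.3, 2)
  ks <- c(); bl_of <- c()
  for (bl in bls) {
    for (r in 1:6) {
      anc <- sample(oracle_sense_codons, 2000, replace = TRUE)
      a <- evolve_codon_sequence(anc, bl / 2, Q = Q)
      b <- evolve_codon_sequence(anc, bl / 2, Q = Q)
      ks <- c(ks, kaks(codon_alignment(a, b), method = "ng86")$Ks)
      bl_of <- c(bl_of, bl)
    }
  }
  rho <- suppressWarnings(cor(bl_of, ks, method = "spearman"))
  expect_gt(rho, 0.95)
})
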