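test_that("rate matrix is a proper generator satisfying detailed balance", {
  set.seed(5)
  w <- runif(61, 0.5, 2)
  pi <- setNames(w / sum(w), names(uniform_codon_frequencies()))
  Q <- codon_rate_matrix(omega = 0.4, kappa = 3, codon_frequencies = pi)
  expect_equal(unname(rowSums(Q)), rep(0, 61), tolerance = 1e-12)
  # detailed balance: pi_i q_ij = pi_j q_ji
  flux <- diag(pi) %*% Q
  expect_equal(flux, t(flux), tolerance = 1e-12, ignore_attr = TRUE)
  # scaled to one nucleotide substitution per site per unit branch length
  expect_equal(-sum(pi * diag(Q)), 3, tolerance = 1e-12)
  # no flow into stops or multi-position neighbours
  nd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (i in sample(61, 5)) {
    for (j in sample(61, 8)) {
      if (i != j && nd(rownames(Q)[i], colnames(Q)[j]) > 1) {
        expect_identical(Q[i, j], 0)
      }
    }
  }
})

test_that("zero branch length and zero omega behave as limiting cases", {
  anc <- sample(oracle_sense_codons, 200, replace = TRUE)
  expect_identical(evolve_codon_sequence(anc, 0, seed = 1), anc)
  # omega = 0: the chain can only make synonymous moves
  ev <- evolve_codon_sequence(anc, 0.5, omega = 0, kappa = 2, seed = 2)
  expect_identical(unname(.GC[ev]), unname(.GC[anc]))
  expect_gt(sum(ev != anc), 0)
  expect_error(evolve_codon_sequence(c("TAA", "ATG"), 0.1),
               "stop or non-sense")
  expect_error(evolve_codon_sequence(anc, -0.1), "non-negative")
})

test_that("identical seeds give identical evolution", {
  anc <- sample(oracle_sense_codons, 300, replace = TRUE)
  e1 <- evolve_codon_sequence(anc, 0.2, omega = 0.5, kappa = 2, seed = 99)
  e2 <- evolve_codon_sequence(anc, 0.2, omega = 0.5, kappa = 2, seed = 99)
  expect_identical(e1, e2)
})

test_that("realized divergence matches the matrix-exponential expectation", {
  bl <- 0.05
  Q <- codon_rate_matrix(1, 1)
  P <- as.matrix(Matrix::expm(Q * bl))
  nd <- outer(rownames(Q), colnames(Q), Vectorize(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }))
  p_exp <- sum((1 / 61) * P * nd) / 3   # expected per-nucleotide p-distance
  n_codons <- 10000L
  anc <- sample(oracle_sense_codons, n_codons, replace = TRUE)
  ev <- evolve_codon_sequence(anc, bl, omega = 1, kappa = 1, seed = 7)
  p_obs <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, anc, ev)) / (3 * n_codons)
  se <- sqrt(p_exp * (1 - p_exp) / (3 * n_codons))
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("evolving t1 then t2 is distributionally equivalent to t1+t2", {
  n <- 20000L
  set.seed(13)
  anc <- sample(oracle_sense_codons, n, replace = TRUE)
  Q <- codon_rate_matrix(0.5, 2)
  two_step <- evolve_codon_sequence(
    evolve_codon_sequence(anc, 0.05, Q = Q), 0.07, Q = Q)
  one_step <- evolve_codon_sequence(anc, 0.12, Q = Q)
  p2 <- mean(two_step != anc)   # codon-level difference fractions
  p1 <- mean(one_step != anc)
  se <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
  expect_lt(abs(p1 - p2), 3 * se)
})

test_that("ortholog set simulation books truth and is byte-reproducible", {
  cfg <- sim_config(n_pairs = 10, codons_per_seq = 40, branch_length = 0.05,
                    paralog_fraction = 0, seed = 4)
  sim <- simulate_ortholog_set(cfg)
  expect_equal(nrow(sim$truth), 10)
  expect_false(any(sim$truth$is_paralog))
  expect_equal(length(sim$fasta_a), 10)
  expect_true(all(grepl("^pair\\d{4}_A$", names(sim$fasta_a))))

  cfg2 <- sim_config(n_pairs = 100, codons_per_seq = 34,
                     paralog_fraction = 0.2, seed = 8)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_ortholog_set(cfg2, out_dir = d1)
  s2 <- simulate_ortholog_set(cfg2, out_dir = d2)
  expect_identical(s1$truth$is_paralog, s2$truth$is_paralog)
  expect_gt(sum(s1$truth$is_paralog), 0)
  for (f in c("species_A.fasta", "species_B.fasta", "ortholog_truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # paralog pairs carry paralog-level divergence in the truth table
  expect_true(all(s1$truth$branch_length_true[s1$truth$is_paralog] >= 0.4))
})

test_that("cohort Ks matches the synonymous expectation from the generator", {
  bl <- 0.16; om <- 0.2; kp <- 2
  Q <- codon_rate_matrix(om, kp)
  P <- as.matrix(Matrix::expm(Q * bl))
  sense <- rownames(Q)
  # expected synonymous differences per codon via pathway counting
  sd_tab <- outer(seq_along(sense), seq_along(sense), Vectorize(function(i, j) {
    count_differences(sense[i], sense[j])[["sd"]]
  }))
  e_sd <- sum((1 / 61) * P * sd_tab)
  s_per_codon <- mean(vapply(sense, function(cd) count_sites(cd)[["s"]],
                             numeric(1)))
  ks_exp <- correct_distance(e_sd / s_per_codon, "JC")
  cfg <- sim_config(n_pairs = 20, codons_per_seq = 2000, omega = om,
                    kappa = kp, branch_length = bl, seed = 17)
  sim <- simulate_ortholog_set(cfg)
  ks_hat <- vapply(seq_len(20), function(i) {
    kaks(codon_alignment(as.character(sim$fasta_a[[i]]),
                         as.character(sim$fasta_b[[i]])),
         method = "ng86")$Ks
  }, numeric(1))
  expect_lt(abs(mean(ks_hat) / ks_exp - 1), 0.10)
})

test_that("variant table simulation honours truth flags", {
  # all clean and shared: the downstream filter keeps everything
  clean <- simulate_variant_tables(200, seed = 3)
  res <- filter_variants(clean$records_a, clean$records_b)
  expect_equal(res$summary$n_retained, 200)
  expect_true(all(clean$truth$clean))

  vt <- simulate_variant_tables(
    1000, shared_fraction = 0.9,
    defect_rates = list(multi_allelic = 0.1, low_depth = 0.1,
                        low_maf = 0.1, low_quality = 0.1), seed = 5)
  res2 <- filter_variants(vt$records_a, vt$records_b)
  # retained set equals the truth table's all-clean shared records exactly
  expect_equal(res2$summary$n_retained, sum(vt$truth$clean))
  truth_keys <- with(vt$truth[vt$truth$clean, ], paste(contig, position))
  kept_keys <- with(res2$retained, paste(contig, position))
  expect_setequal(kept_keys, truth_keys)
  # depth-flagged shared sites all fail (spot check by rule)
  dp_keys <- with(vt$truth[vt$truth$low_depth, ], paste(contig, position))
  expect_length(intersect(dp_keys, kept_keys), 0)
})

test_that("read simulation truth matches the trimming filter", {
  rd <- simulate_reads(1000, defect_rates = list(high_n = 0.05,
                                                 low_quality = 0.05,
                                                 short = 0.05), seed = 9)
  tr <- trim_reads(rd)
  expect_equal(tr$report$retained, sum(rd$truth$clean))
  expect_setequal(names(tr$sequences), rd$truth$read_id[rd$truth$clean])
  # all-clean input passes untouched
  rd0 <- simulate_reads(100, seed = 10)
  tr0 <- trim_reads(rd0)
  expect_equal(tr0$report$retained, 100)
})

test_that("simulator outputs on disk are byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  simulate_variant_tables(100, defect_rates = list(low_depth = 0.2),
                          seed = 11, out_dir = d1)
  simulate_variant_tables(100, defect_rates = list(low_depth = 0.2),
                          seed = 11, out_dir = d2)
  for (f in c("group_A.vcf", "group_B.vcf", "variant_truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  simulate_reads(50, defect_rates = list(short = 0.1), seed = 12,
                 out_path = f1)
  simulate_reads(50, defect_rates = list(short = 0.1), seed = 12,
                 out_path = f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
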