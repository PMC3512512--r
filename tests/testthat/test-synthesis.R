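test_that("genotype generator hits the target heterozygosity", {
  # closed form for the Beta(0.6, 1.6) MAF prior: 2(E[p] - E[p^2]) = 0.2727
  a <- 0.6; b <- 1.6
  het_expected <- 2 * (a / (a + b) - a * (a + 1) / ((a + b) * (a + b + 1)))
  expect_equal(het_expected, 0.2727, tolerance = 2e-4)
  cfg <- sim_config(n_samples = 1, n_chromosomes = 100, snps_per_chr = 1000,
                    seed = 1)
  g <- simulate_genotypes(cfg)
  het <- mean(g$germ_a == 1L & g$germ_b == 1L)
  expect_equal(het, het_expected, tolerance = 0.01)
  # overrides
  g5 <- simulate_genotypes(sim_config(n_samples = 1, n_chromosomes = 2,
                                      snps_per_chr = 2000, maf_fixed = 0.5,
                                      seed = 2))
  expect_equal(mean(g5$germ_a == 1L & g5$germ_b == 1L), 0.5,
               tolerance = 0.03)
  g0 <- simulate_genotypes(sim_config(n_samples = 2, n_chromosomes = 1,
                                      snps_per_chr = 500, maf_fixed = 0,
                                      seed = 3))
  expect_true(all(g0$germ_b == 0L))
})

test_that("aberrations transform allele copies as specified", {
  cfg <- sim_config(n_samples = 20, n_chromosomes = 4, snps_per_chr = 500,
                    aberrations = list(aberration(0.1, "gain",
                                                  recurrence = 0.7,
                                                  location = "fixed")),
                    seed = 4)
  g <- simulate_genotypes(cfg)
  tr <- apply_aberrations(g, cfg)
  # exactly floor(0.7 * 20) samples share identical bp bounds
  expect_equal(nrow(tr$regions), 14L)
  expect_equal(nrow(unique(tr$regions[c("chromosome", "start_bp", "end_bp")])),
               1L)
  aber <- tr$cn_a != g$germ_a | tr$cn_b != g$germ_b
  # gains add exactly one allele copy
  expect_true(all((tr$cn_a + tr$cn_b - (g$germ_a + g$germ_b))[aber] == 1L))
  # heterozygotes become 2+1 with expected LH 2/3
  het_aber <- aber & g$germ_a == 1L & g$germ_b == 1L
  expect_true(all(expected_lh(tr$cn_a[het_aber], tr$cn_b[het_aber]) == 2 / 3))
})

test_that("LOH keeps two copies but erases heterozygosity", {
  cfg <- sim_config(n_samples = 4, n_chromosomes = 2, snps_per_chr = 400,
                    aberrations = list(aberration(0.25, "loh")), seed = 5)
  g <- simulate_genotypes(cfg)
  tr <- apply_aberrations(g, cfg)
  changed <- tr$cn_a != g$germ_a
  expect_true(any(changed))
  expect_true(all((tr$cn_a + tr$cn_b)[changed] == 2L))
  expect_true(all(expected_lh(tr$cn_a[changed], tr$cn_b[changed]) == 0))
  # truth mask: aberrated fraction approximately the configured fraction
  expect_equal(mean(!tr$normal), 0.25, tolerance = 0.05)
})

test_that("noise-free rendering reproduces the analytic LH surface", {
  cfg <- sim_config(n_samples = 3, n_chromosomes = 2, snps_per_chr = 500,
                    aberrations = list(aberration(0.3, "gain")),
                    noise_sd = 0, probe_log_sd = 0.4, purity = 1, seed = 6)
  sim <- simulate_dataset(cfg)
  lh <- compute_lh(sim$signals$theta_a, sim$signals$theta_b)
  snp <- sim$config$n_chromosomes * sim$config$snps_per_chr
  is_snp <- sim$signals$annotation$probe_class == "SNP"
  het_normal <- sim$truth$cn_a == 1L & sim$truth$cn_b == 1L
  # balanced alleles: the floor cancels and LH is exactly 1
  expect_true(all(abs(lh[het_normal] - 1) < 1e-12))
  gained_het <- (sim$truth$cn_a == 2L & sim$truth$cn_b == 1L) |
    (sim$truth$cn_a == 1L & sim$truth$cn_b == 2L)
  # 2+1 copies: floor-perturbed 2/3
  expect_true(all(abs(lh[gained_het] - 2 / 3) < 0.02))
})

test_that("purity pulls effective copies toward the germline", {
  cfg <- sim_config(n_samples = 2, n_chromosomes = 1, snps_per_chr = 300,
                    aberrations = list(aberration(0.5, "deletion")),
                    noise_sd = 0, probe_log_sd = 0, purity = 0.5, seed = 7)
  sim <- simulate_dataset(cfg)
  t1 <- total_signal(sim$signals)
  del_snp <- !sim$truth$normal &
    (sim$signals$annotation$probe_class == "SNP")
  i1 <- which(del_snp, arr.ind = TRUE)[1, ]
  # one-copy deletion at purity 0.5: effective total 1.5, plus the floor
  # 2 * 0.05 on unit probe constants
  expect_equal(unname(t1[i1[1], i1[2]]), 1.6, tolerance = 1e-9)
})

test_that("simulation is deterministic and composes into a valid set", {
  cfg <- sim_config(n_samples = 2, n_chromosomes = 1, snps_per_chr = 100,
                    cn_probes_per_chr = 10, seed = 9)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$signals$theta_a, s2$signals$theta_a)
  expect_identical(s1$truth$cn_total, s2$truth$cn_total)
  expect_s3_class(s1$signals, "signal_set")
  expect_true(all(s1$truth$cn_total[s1$truth$normal] == 2L))
  # truth normal fraction tracks the configured aberration load
  cfg2 <- sim_config(n_samples = 6, n_chromosomes = 5, snps_per_chr = 400,
                     seed = 10)
  frac <- sum(vapply(cfg2$aberrations, `[[`, numeric(1), "fraction"))
  sim2 <- simulate_dataset(cfg2)
  expect_equal(mean(!sim2$truth$normal), frac, tolerance = 0.04)
})
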