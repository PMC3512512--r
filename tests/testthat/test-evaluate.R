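test_that("ROC handles the canonical cases", {
  r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(roc_curve(c(4, 3, 2, 1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_curve(c(1, 2, 3, 4), c(1, 1, 0, 0))$auc, 0.0)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(1)
  null <- roc_curve(rnorm(10000), rbinom(10000, 1, 0.5))
  expect_equal(null$auc, 0.5, tolerance = 0.02)
  expect_true(all(diff(null$fpr) >= 0) && all(diff(null$tpr) >= 0))
})

test_that("ROC agrees with the rank-statistic oracle, ties included", {
  set.seed(33)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    values <- sample(1:5, n, replace = TRUE)   # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_curve(values, labels)$auc, auc_by_ranks(values, labels),
                 tolerance = 1e-12, info = paste("rep", rep))
  }
})

test_that("ROC agrees with pROC on a larger instance", {
  skip_if_not_installed("pROC")
  set.seed(3)
  values <- rnorm(500) + rbinom(500, 1, 0.5)
  labels <- as.integer(values + rnorm(500) > 0.5)
  ours <- roc_curve(values, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, values, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("region ROC excludes the safety zone and detects jumps", {
  ann <- probe_annotation(sprintf("p%03d", 1:100), "chr1",
                          seq(1e6, 1e8, length.out = 100), "SNP")
  set.seed(4)
  cn <- matrix(c(rep(1, 50), rep(2, 50)) + rnorm(100, 0, 0.05), 100, 1,
               dimnames = list(ann$probe_id, "s1"))
  ra <- genome_region("chr1", 1, 5e7)
  rb <- genome_region("chr1", 5e7 + 1, 1e8)
  saf <- genome_region("chr1", 4.5e7, 5.5e7)
  r <- region_roc(cn, ann, "s1", ra, rb, saf)
  expect_equal(r$auc, 1.0)
  noisy <- cn + rnorm(100, 0, 0.3)
  expect_gte(region_roc(noisy, ann, "s1", ra, rb, saf)$auc,
             region_roc(noisy, ann, "s1", ra, rb)$auc - 0.05)
  expect_error(region_roc(cn, ann, "s1", ra, rb,
                          genome_region("chr1", 1, 1e8)), "empty")
  expect_error(region_roc(cn, ann, "s1", ra,
                          genome_region("chr1", 4e7, 1e8)), "overlap")
})

test_that("baseline references behave as unmasked medians", {
  t1 <- rbind(p1 = c(1, 2, 3), p2 = c(5, 4, 6))
  colnames(t1) <- paste0("s", 1:3)
  expect_equal(mts_reference(t1), c(p1 = 2, p2 = 5))
  # MTS equals the masked reference under an all-ones mask
  allmask <- matrix(1L, 2, 3, dimnames = dimnames(t1))
  expect_equal(mts_reference(t1), snp_reference(t1, allmask)$reference)
  expect_equal(mcs_reference(t1, c("s1", "s2", "s3")), mts_reference(t1))
  expect_equal(mcs_reference(t1, "s2"), c(p1 = 2, p2 = 4))
  expect_error(mcs_reference(t1, "nope"), "unknown control")
})

.in_region_test <- function(ann, reg) {
  ann$chromosome == reg$chromosome & ann$position >= reg$start_bp &
    ann$position <= reg$end_bp
}

test_that("a recurrent gain biases the all-tumor median reference", {
  # 70% of samples carry a gain at a fixed locus; the all-sample median
  # then tracks the aberrated signal level (~1.5x the normal level)
  cfg <- sim_config(n_samples = 20, n_chromosomes = 4, snps_per_chr = 300,
                    aberrations = list(aberration(0.08, "gain",
                                                  recurrence = 0.7,
                                                  location = "fixed")),
                    noise_sd = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  t1 <- total_signal(sim$signals)
  reg <- sim$truth$regions[1, ]
  in_reg <- .in_region_test(sim$signals$annotation, reg)
  aber_samples <- sim$truth$regions$sample
  normal_cols <- setdiff(seq_len(20), aber_samples)
  mref <- mts_reference(t1)
  ratio <- mref[in_reg] / apply(t1[in_reg, normal_cols], 1, median)
  expect_equal(median(ratio), 1.5, tolerance = 0.03)
})
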