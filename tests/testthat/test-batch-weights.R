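make_mask_ann <- function(counts, n_samples) {
  # counts: per-SNP number of normal samples
  J <- length(counts)
  mask <- t(vapply(counts, function(k)
    c(rep(1L, k), rep(0L, n_samples - k)), integer(n_samples)))
  ann <- probe_annotation(paste0("p", seq_len(J)), "chr1",
                          seq_len(J) * 10L, rep("SNP", J))
  rownames(mask) <- ann$probe_id
  list(mask = mask, ann = ann)
}

test_that("the SNP set prefers loci normal in many samples", {
  x <- make_mask_ann(c(5L, 2L, 4L), 6L)
  sel <- select_snp_set(x$mask, x$ann, size = 2L, seed = 1L)
  expect_identical(sort(x$ann$probe_id[sel$indices]), c("p1", "p3"))
  expect_identical(unname(sel$n_normal), c(5, 4))
  # size larger than the SNP count returns everything
  expect_length(select_snp_set(x$mask, x$ann, size = 99L, seed = 1L)$indices,
                3L)
  # ties are broken deterministically under a fixed seed
  y <- make_mask_ann(rep(3L, 10L), 6L)
  s1 <- select_snp_set(y$mask, y$ann, size = 4L, seed = 5L)
  s2 <- select_snp_set(y$mask, y$ann, size = 4L, seed = 5L)
  expect_identical(s1$indices, s2$indices)
  expect_error(select_snp_set(0L * x$mask, x$ann, seed = 1L), "all zero")
})

test_that("filled signals substitute the reference outside normal calls", {
  t1 <- rbind(p1 = c(1, 2, 3), p2 = c(4, 5, 6), p3 = c(7, 8, 9))
  colnames(t1) <- paste0("s", 1:3)
  mask <- rbind(p1 = c(1L, 1L, 1L), p2 = c(1L, 0L, 1L), p3 = c(0L, 0L, 0L))
  ref <- snp_reference(t1, mask)
  ss <- list(indices = 1:3, n_normal = rowSums(mask))
  filled <- build_filled_signals(t1, mask, ref, ss)
  expect_equal(filled["p1", ], c(s1 = 1, s2 = 2, s3 = 3))   # untouched
  expect_equal(unname(filled["p2", 2]), 5)                  # masked -> ref
  expect_equal(unname(filled["p3", ]), rep(8, 3))           # full fallback
})

test_that("weight estimation finds duplicated samples and obeys constraints", {
  set.seed(17)
  S <- 120
  base <- exp(rnorm(S, 0, 0.3))
  m <- cbind(s1 = base * exp(rnorm(S, 0, 0.02)), s2 = NA, s3 = NA)
  m[, 2] <- m[, 1]                                  # exact duplicate
  m[, 3] <- exp(rnorm(S, 0, 0.3))                   # unrelated
  g <- estimate_weights(m)
  expect_equal(unname(g[1, 2]), 1, tolerance = 0.05)
  expect_equal(unname(g[1, 3]), 0, tolerance = 0.05)
  expect_true(all(g >= 0))
  expect_true(all(diag(g) == 0))
  expect_error(estimate_weights(cbind(s1 = rep(2, 5), s2 = 1:5)),
               "degenerate")
})

test_that("an all-nonnegative unconstrained solution is returned as-is", {
  set.seed(23)
  S <- 80
  phi <- rnorm(S, 0, 0.5)
  m <- exp(phi + matrix(rnorm(S * 4, 0, 0.05), S))
  colnames(m) <- paste0("s", 1:4)
  g <- estimate_weights(m)
  for (i in 1:4) {
    ols <- lm.fit(log(m)[, -i, drop = FALSE], log(m)[, i])$coefficients
    if (all(ols >= 0))
      expect_equal(unname(g[i, -i]), unname(ols), tolerance = 1e-10)
  }
})

test_that("the active-set solver attains the quadratic-programming optimum", {
  skip_if_not_installed("pracma")
  set.seed(42)
  for (k in 1:10) {
    I <- sample(3:6, 1)
    S <- sample(20:50, 1)
    m <- exp(rnorm(S, 0, 0.3) + matrix(rnorm(S * I, 0, 0.15), S))
    colnames(m) <- paste0("s", seq_len(I))
    g <- estimate_weights(m)
    obj <- attr(g, "objective")
    for (i in seq_len(I)) {
      A <- log(m)[, -i, drop = FALSE]
      qp <- pracma::lsqnonneg(A, log(m)[, i])
      qp_obj <- sqrt(sum((log(m)[, i] - A %*% qp$x)^2))
      expect_lt(abs(obj[i] - qp_obj) / qp_obj, 1e-6)
    }
  }
})

test_that("weights never do worse than uniform weighting", {
  set.seed(9)
  m <- exp(rnorm(60, 0, 0.4) + matrix(rnorm(60 * 5, 0, 0.2), 60))
  colnames(m) <- paste0("s", 1:5)
  g <- estimate_weights(m)
  obj <- attr(g, "objective")
  L <- log(m)
  for (i in 1:5) {
    uni <- sqrt(sum((L[, i] - rowMeans(L[, -i, drop = FALSE]))^2))
    expect_lte(obj[i], uni + 1e-12)
  }
})

test_that("the weighted median minimizes weighted absolute deviation", {
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(weighted_median(c(1, 10), c(3, 1)), 1)
  expect_equal(weighted_median(c(1, 3), c(1, 1)), 2)
  expect_error(weighted_median(1:3, c(0, 0, 0)), "positive")
  set.seed(71)
  for (rep in 1:50) {
    n <- sample(1:9, 1)
    x <- round(rnorm(n), 2)
    w <- round(rexp(n) + 0.05, 2)
    wm <- weighted_median(x, w)
    expect_true(any(abs(wm - wmedian_bruteforce(x, w)) < 1e-12),
                info = paste("rep", rep))
    # equal weights reproduce the ordinary median
    expect_equal(weighted_median(x, rep(2, n)), median(x))
    # weight-scale invariance
    expect_identical(weighted_median(x, w), weighted_median(x, 10 * w))
  }
})

test_that("weighted references generalize the plain masked median", {
  set.seed(12)
  J <- 30; I <- 5
  t1 <- matrix(2 * exp(rnorm(J * I, 0, 0.2)), J, I,
               dimnames = list(paste0("p", 1:J), paste0("s", 1:I)))
  mask <- matrix(rbinom(J * I, 1, 0.8), J, I, dimnames = dimnames(t1))
  mask[1, ] <- 0L                        # no normal sample at p1
  uniform <- matrix(1, I, I) - diag(I)
  wr <- weighted_snp_reference(t1, mask, uniform)
  plain <- snp_reference(t1, mask)
  for (i in seq_len(I))
    for (j in 2:J) {
      normal_k <- which(mask[j, ] == 1L & seq_len(I) != i)
      if (length(normal_k) == 0) next
      expect_equal(wr$reference[j, i],
                   median(t1[j, mask[j, ] == 1L & seq_len(I) != i]))
    }
  # the all-fallback probe uses the plain reference and is flagged
  expect_true(all(wr$fallback[1, ]))
  expect_equal(unname(wr$reference[1, 1]), unname(plain$reference[1]))
  # a weight row concentrated on one sample returns that sample's signal
  conc <- matrix(0, I, I); conc[1, 3] <- 5
  wc <- weighted_snp_reference(t1, mask, conc)
  j_ok <- which(mask[, 3] == 1L)[1]
  expect_equal(unname(wc$reference[j_ok, 1]), unname(t1[j_ok, 3]))
  # scaling a weight row leaves the reference unchanged
  expect_equal(weighted_snp_reference(t1, mask, 10 * uniform)$reference,
               wr$reference)
})
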