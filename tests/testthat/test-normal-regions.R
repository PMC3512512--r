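make_segments <- function(props, sample = "s1", chrom = "chr1",
                          n_markers = 100L) {
  k <- length(props)
  data.frame(sample_id = sample, chromosome = chrom,
             start_marker = seq(0L, by = n_markers, length.out = k),
             end_marker = seq(n_markers, by = n_markers, length.out = k),
             start_bp = seq(1L, by = 1000L, length.out = k),
             end_bp = seq(1000L, by = 1000L, length.out = k),
             n_markers = n_markers,
             n_informative = ifelse(is.na(props), 0L, n_markers),
             hncn_proportion = props, flagged = FALSE)
}

test_that("segments are labeled by their HNCN proportion", {
  st <- label_segments(make_segments(c(0.183, 0.086, 0.135, NA)))
  # 18.3% is comfortably normal, 8.6% aberrated, the exact threshold counts
  # as normal, and an uninformative segment is aberrated + flagged
  expect_identical(st$normal_label, c(1L, 0L, 1L, 0L))
  expect_identical(st$flagged, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("raising the threshold never turns aberrated into normal", {
  props <- seq(0, 0.4, by = 0.02)
  st <- make_segments(props)
  for (th in c(0.05, 0.135, 0.2, 0.35)) {
    lo <- label_segments(st, th)$normal_label
    hi <- label_segments(st, th + 0.05)$normal_label
    expect_true(all(hi <= lo))
  }
})

test_that("the mask propagates segment labels to SNP and CN probes", {
  ann <- probe_annotation(
    probe_id = c("s1", "s2", "s3", "s4", "c_in_normal", "c_in_aber",
                 "c_past_end"),
    chromosome = "chr1",
    position = c(100L, 200L, 300L, 400L, 150L, 350L, 450L),
    probe_class = c(rep("SNP", 4), rep("CN", 3)))
  segs <- data.frame(sample_id = "t1", chromosome = "chr1",
                     start_marker = c(0L, 2L), end_marker = c(2L, 4L),
                     start_bp = c(100L, 300L), end_bp = c(200L, 400L),
                     n_markers = 2L, n_informative = 2L,
                     hncn_proportion = c(0.3, 0.0), flagged = FALSE)
  segs <- label_segments(segs)
  mask <- build_normal_mask(segs, ann)
  expect_identical(mask["c_in_normal", "t1"], 1L)   # contained in normal
  expect_identical(mask["c_in_aber", "t1"], 0L)     # contained in aberrated
  expect_identical(mask["c_past_end", "t1"], 0L)    # nearest = terminal seg
  expect_identical(unname(mask[c("s1", "s2", "s3", "s4"), "t1"]),
                   c(1L, 1L, 0L, 0L))
  # a CN probe just past a *normal* terminal segment inherits its label
  segs2 <- segs
  segs2$hncn_proportion <- c(0.0, 0.3)
  segs2 <- label_segments(segs2)
  mask2 <- build_normal_mask(segs2, ann)
  expect_identical(mask2["c_past_end", "t1"], 1L)
})

test_that("degenerate mask cases warn", {
  ann <- probe_annotation(c("a", "b", "lonely_cn"),
                          c("chr1", "chr1", "chr9"),
                          c(10L, 20L, 10L), c("SNP", "SNP", "CN"))
  segs <- label_segments(data.frame(
    sample_id = "t1", chromosome = "chr1", start_marker = 0L,
    end_marker = 2L, start_bp = 10L, end_bp = 20L, n_markers = 2L,
    n_informative = 2L, hncn_proportion = 0.0, flagged = FALSE))
  expect_warning(expect_warning(mask <- build_normal_mask(segs, ann),
                                "without SNP probes"),
                 "no normal probes")
  expect_identical(unname(mask[, "t1"]), c(0L, 0L, 0L))
})

test_that("mask recovers the simulated normal regions at marker level", {
  res <- small_sim_fit(seed = 14, n_samples = 5, n_chr = 5,
                       snps_per_chr = 1000)
  pred <- res$fit$mask == 1L
  truth <- res$sim$truth$normal
  sens <- mean(pred[truth])
  spec <- mean(!pred[!truth])
  expect_gte(sens, 0.90)
  expect_gte(spec, 0.90)
  # SNP-probe mask is constant within each segment
  segs <- res$fit$segments
  ann <- res$sim$signals$annotation
  snp_rows <- which(ann$probe_class == "SNP")
  chr1 <- segs[segs$chromosome == ann$chromosome[1] &
                 segs$sample_id == colnames(res$fit$mask)[1], ]
  in_chr <- snp_rows[ann$chromosome[snp_rows] == ann$chromosome[1]]
  for (k in seq_len(nrow(chr1))) {
    vals <- res$fit$mask[in_chr[(chr1$start_marker[k] + 1):chr1$end_marker[k]], 1]
    expect_length(unique(vals), 1L)
  }
})
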