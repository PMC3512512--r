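# fixtures built in code: a tiny deterministic signal set and file writers

tiny_annotation <- function() {
  probe_annotation(
    probe_id = c("snp1", "snp2", "snp3", "cn1"),
    chromosome = c("chr1", "chr1", "chr2", "chr1"),
    position = c(100L, 200L, 150L, 250L),
    probe_class = c("SNP", "SNP", "SNP", "CN"))
}

tiny_signal_set <- function() {
  ann <- tiny_annotation()
  ta <- matrix(c(1.0, 2.0, 0.5, 1.5, 2.5, 0.8), 3, 2,
               dimnames = list(c("snp1", "snp2", "snp3"), c("A", "B")))
  tb <- matrix(c(1.0, 1.0, 0.0, 1.5, 1.2, 0.1), 3, 2,
               dimnames = list(c("snp1", "snp2", "snp3"), c("A", "B")))
  tc <- matrix(c(1.7, 2.1), 1, 2, dimnames = list("cn1", c("A", "B")))
  signal_set(ta, tb, ann, tc)
}

write_matrix_fixture <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_signal_fixtures <- function(signals, dir) {
  write_matrix_fixture(signals$theta_a, file.path(dir, "theta_a.tsv"))
  write_matrix_fixture(signals$theta_b, file.path(dir, "theta_b.tsv"))
  if (nrow(signals$theta_cn))
    write_matrix_fixture(signals$theta_cn, file.path(dir, "theta_cn.tsv"))
  write.table(as.data.frame(signals$annotation),
              file.path(dir, "annotation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  dir
}

# brute-force weighted median: minimize sum w|x - m| over data points and
# midpoints of adjacent order statistics
wmedian_bruteforce <- function(x, w) {
  xs <- sort(unique(x))
  cand <- sort(c(xs, (head(xs, -1) + tail(xs, -1)) / 2))
  loss <- vapply(cand, function(m) sum(w * abs(x - m)), numeric(1))
  cand[which(loss <= min(loss) + 1e-12)]
}

# rank-based (Wilcoxon U) AUC, tie-corrected: independent of the sweep code
auc_by_ranks <- function(values, labels) {
  r <- rank(values)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

# quick full simulation + fit at small scale
small_sim_fit <- function(seed = 3, n_samples = 6, n_chr = 4,
                          snps_per_chr = 400, ...) {
  sim <- simulate_dataset(sim_config(n_samples = n_samples,
                                     n_chromosomes = n_chr,
                                     snps_per_chr = snps_per_chr,
                                     cn_probes_per_chr = 20,
                                     seed = seed, ...))
  fit <- nsa(sim$signals, n_perm = 500, seed = seed)
  list(sim = sim, fit = fit)
}
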