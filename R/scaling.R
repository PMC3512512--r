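#' Total probe signal
#'
#' First-stage signal used by the scaling: the sum of the two allele
#' signals for SNP probes and the total signal for CN probes, assembled in
#' annotation order.
#'
#' @param signals a \code{\link{signal_set}}.
#' @return numeric matrix (all probes x samples).
#' @export
total_signal <- function(signals) {
  stopifnot(inherits(signals, "signal_set"))
  tot_snp <- signals$theta_a + signals$theta_b
  out <- rbind(tot_snp, signals$theta_cn)
  out[signals$annotation$probe_id, , drop = FALSE]
}

#' Per-SNP reference from normal samples
#'
#' For every probe, the median of the total signal over the samples labeled
#' normal there. A probe with no normal sample falls back to the median
#' over all samples (the all-tumor-median behavior) and is flagged so users
#' can drop such loci: when every sample is aberrated at a locus no
#' reference-free method can anchor it.
#'
#' @param theta1 total-signal matrix from \code{\link{total_signal}}.
#' @param mask a \code{\link{build_normal_mask}} matrix (same shape).
#' @return list with \code{reference} (length-J vector) and \code{fallback}
#'   (logical vector marking all-aberrated probes).
#' @export
snp_reference <- function(theta1, mask) {
  if (!all(dim(theta1) == dim(mask))) stop("theta1 and mask shapes differ")
  n_norm <- rowSums(mask == 1L)
  ref <- numeric(nrow(theta1))
  fallback <- n_norm == 0L
  for (j in which(!fallback))
    ref[j] <- stats::median(theta1[j, mask[j, ] == 1L])
  if (any(fallback))
    ref[fallback] <- apply(theta1[fallback, , drop = FALSE], 1L, stats::median)
  names(ref) <- rownames(theta1)
  list(reference = ref, fallback = fallback)
}

#' Scale signals across SNPs
#'
#' Divides each probe's total signal by its reference and multiplies by 2,
#' so that the value of a normal sample at a normal probe lands near 2
#' copies. With a weighted (batch-aware) reference the divisor differs per
#' sample.
#'
#' @param theta1 total-signal matrix.
#' @param ref either a length-J vector (plain mode) or a J x I matrix
#'   (batch mode) of references, all positive.
#' @return matrix of per-SNP scaled values.
#' @export
scale_by_snp <- function(theta1, ref) {
  if (is.matrix(ref)) {
    if (!all(dim(ref) == dim(theta1))) stop("reference matrix shape differs")
    bad <- which(ref <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("nonpositive reference for probe ", rownames(theta1)[bad[1L, 1L]])
    return(2 * theta1 / ref)
  }
  if (length(ref) != nrow(theta1)) stop("reference length differs from probes")
  if (any(ref <= 0))
    stop("nonpositive reference for probe ",
         rownames(theta1)[which(ref <= 0)[1L]])
  2 * theta1 / ref
}

#' Per-sample reference from normal probes
#'
#' For every sample, the median of the per-SNP scaled values over its
#' normal probes; expected to be close to 2. A sample with no normal probe
#' falls back to the median over all probes and is flagged.
#'
#' @param theta2 matrix from \code{\link{scale_by_snp}}.
#' @param mask normal mask (same shape).
#' @return list with \code{reference} (length-I vector) and \code{fallback}
#'   (logical per sample).
#' @export
sample_reference <- function(theta2, mask) {
  if (!all(dim(theta2) == dim(mask))) stop("theta2 and mask shapes differ")
  n_norm <- colSums(mask == 1L)
  fallback <- n_norm == 0L
  ref <- vapply(seq_len(ncol(theta2)), function(i) {
    if (fallback[i]) stats::median(theta2[, i])
    else stats::median(theta2[mask[, i] == 1L, i])
  }, numeric(1L))
  names(ref) <- colnames(theta2)
  list(reference = ref, fallback = fallback)
}

#' Scale signals across samples
#'
#' Rescales each sample so the median of its normal probes is exactly 2
#' copies.
#'
#' @param theta2 matrix from \code{\link{scale_by_snp}}.
#' @param sample_ref positive length-I vector from
#'   \code{\link{sample_reference}}.
#' @return matrix of final copy-number estimates.
#' @export
scale_by_sample <- function(theta2, sample_ref) {
  if (length(sample_ref) != ncol(theta2))
    stop("sample reference length differs from samples")
  if (any(sample_ref <= 0)) stop("nonpositive sample reference")
  sweep(theta2, 2L, sample_ref, function(x, r) 2 * x / r)
}

#' Run the full two-step scaling
#'
#' Composes the four scaling steps: per-SNP reference over normal samples
#' (plain median, or weighted median when a weight matrix from
#' \code{\link{estimate_weights}} is supplied), scaling across SNPs,
#' per-sample reference over normal probes, scaling across samples. The
#' composition can be iterated (each iteration re-derives both references
#' from the previous iteration's copy numbers with the normal mask held
#' fixed); improvement beyond the first iteration is typically negligible
#' (mean absolute change on the order of 0.001 copies) and the default is
#' a single pass.
#'
#' @param signals a \code{\link{signal_set}}.
#' @param mask normal mask over all probes (see
#'   \code{\link{build_normal_mask}}).
#' @param weights optional I x I nonnegative weight matrix with zero
#'   diagonal for batch-aware references.
#' @param n_iter number of iterations (>= 1).
#' @return An object of class \code{"cn_matrix"}: list with \code{values}
#'   (copy-number matrix), \code{flags} (list of per-probe and per-sample
#'   fallback indicators), \code{references} (the last iteration's SNP and
#'   sample references) and \code{iteration_delta} (mean absolute change in
#'   copy number between successive iterations; length \code{n_iter - 1}).
#' @export
run_scaling <- function(signals, mask, weights = NULL, n_iter = 1L) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  theta1 <- total_signal(signals)
  if (!all(dim(theta1) == dim(mask)))
    stop("mask shape does not match the probe x sample layout")
  cur <- theta1
  deltas <- numeric(0)
  prev_values <- NULL
  snp_ref <- NULL; samp_ref <- NULL
  for (it in seq_len(n_iter)) {
    if (is.null(weights)) {
      snp_ref <- snp_reference(cur, mask)
      theta2 <- scale_by_snp(cur, snp_ref$reference)
    } else {
      snp_ref <- weighted_snp_reference(cur, mask, weights)
      theta2 <- scale_by_snp(cur, snp_ref$reference)
    }
    samp_ref <- sample_reference(theta2, mask)
    values <- scale_by_sample(theta2, samp_ref$reference)
    if (!is.null(prev_values))
      deltas <- c(deltas, mean(abs(values - prev_values)))
    prev_values <- values
    cur <- values
  }
  structure(list(values = prev_values,
                 flags = list(probe_fallback = snp_ref$fallback,
                              sample_fallback = samp_ref$fallback),
                 references = list(snp = snp_ref$reference,
                                   sample = samp_ref$reference),
                 iteration_delta = deltas),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat("cn_matrix:", nrow(x$values), "probes x", ncol(x$values), "samples\n")
  cat(sprintf("  value range: [%.3f, %.3f]; %d probe fallback(s), %d sample fallback(s)\n",
              min(x$values), max(x$values), sum(x$flags$probe_fallback),
              sum(x$flags$sample_fallback)))
  if (length(x$iteration_delta))
    cat("  mean |change| per iteration:",
        paste(signif(x$iteration_delta, 3), collapse = ", "), "\n")
  invisible(x)
}
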