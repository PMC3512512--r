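#' Level of heterozygosity from allele signals
#'
#' The level of heterozygosity (LH) of a SNP in a sample is
#' \deqn{LH = 2 \min(\theta^A, \theta^B) / (\theta^A + \theta^B),}
#' a continuous score in [0, 1] that is 1 when both allele signals are
#' balanced (a heterozygote with equal allele copies) and 0 when one allele
#' signal vanishes (homozygote, or strong allelic imbalance). Entries where
#' \eqn{\theta^A + \theta^B = 0} carry no evidence and are returned as
#' \code{NA}.
#'
#' @param theta_a,theta_b nonnegative numeric matrices (or vectors) of the
#'   same shape.
#' @return numeric matrix of LH values in [0, 1], \code{NA} where both
#'   signals are zero.
#' @seealso \code{\link{compute_lh_from_baf}} for the equivalent B-allele
#'   fraction form, \code{\link{expected_lh}} for the noise-free value at a
#'   given genotype.
#' @export
compute_lh <- function(theta_a, theta_b) {
  if (length(theta_a) != length(theta_b))
    stop("theta_a and theta_b must have the same shape")
  if (any(theta_a < 0, na.rm = TRUE) || any(theta_b < 0, na.rm = TRUE))
    stop("allele signals must be nonnegative")
  tot <- theta_a + theta_b
  lh <- 2 * pmin(theta_a, theta_b) / tot
  lh[tot <= 0] <- NA_real_
  lh
}

#' Level of heterozygosity from B-allele fractions
#'
#' Equivalent form of \code{\link{compute_lh}} in terms of the B-allele
#' fraction \eqn{\beta = \theta^B/(\theta^A+\theta^B)}:
#' \deqn{LH = 2 \min(\beta, 1 - \beta).}
#' Missing \eqn{\beta} propagates to missing LH.
#'
#' @param beta numeric matrix (or vector) of B-allele fractions in [0, 1].
#' @return numeric matrix of LH values; \code{NA} where \code{beta} is.
#' @export
compute_lh_from_baf <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("B-allele fractions must lie in [0, 1]")
  2 * pmin(beta, 1 - beta)
}

#' Noise-free LH of a genotype
#'
#' With signals exactly proportional to allele copies, a genotype carrying
#' \code{n_a} copies of allele A and \code{n_b} of allele B has
#' \deqn{LH = 2 \min(n_a, n_b) / (n_a + n_b).}
#' A balanced heterozygote (1,1) gives 1; any homozygote gives 0; a
#' one-allele gain (2,1) gives 2/3; (3,1) gives 1/2; a homozygous deletion
#' (0,0) is undefined (\code{NA}).
#'
#' @param n_a,n_b nonnegative integer allele copy counts (vectorized).
#' @return numeric vector of expected LH values.
#' @export
expected_lh <- function(n_a, n_b) {
  if (any(n_a < 0) || any(n_b < 0)) stop("allele copy counts must be >= 0")
  compute_lh(as.numeric(n_a), as.numeric(n_b))
}

#' Default LH threshold for balanced-heterozygote calls
#'
#' The hardest aberration to tell apart from a normal heterozygote is a
#' single-copy gain: its heterozygotes sit at LH = 2/3 (genotype with allele
#' copies 2 and 1) while normal heterozygotes sit at LH = 1 (copies 1 and
#' 1), and normal-tissue contamination only pushes the gain value upwards.
#' The default threshold is therefore the midpoint of the two expectations,
#' 5/6, derived here from \code{\link{expected_lh}} rather than stated as a
#' literal.
#'
#' @return the scalar 5/6.
#' @export
default_lh_threshold <- function() {
  (expected_lh(1, 1) + expected_lh(2, 1)) / 2
}

#' Call heterozygous neutral-copy-number SNPs (HNCNs)
#'
#' Binarizes an LH matrix: entries with non-missing LH strictly above the
#' threshold are called HNCN (1), everything else - including missing LH
#' from dead probes - is 0. The strict inequality means a value exactly at
#' the threshold is not called; ties are measure-zero on real intensities.
#'
#' @param lh LH matrix from \code{\link{compute_lh}}.
#' @param threshold call threshold in (0, 1); default
#'   \code{\link{default_lh_threshold}()}.
#' @return An object of class \code{"hncn_calls"}: list with \code{calls}
#'   (binary matrix, same dimnames as \code{lh}), \code{informative}
#'   (logical matrix, FALSE where LH was missing) and \code{threshold}.
#' @export
call_hncn <- function(lh, threshold = default_lh_threshold()) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single number in (0, 1)")
  lh <- as.matrix(lh)
  informative <- !is.na(lh)
  calls <- matrix(0L, nrow(lh), ncol(lh), dimnames = dimnames(lh))
  calls[informative & lh > threshold] <- 1L
  structure(list(calls = calls, informative = informative,
                 threshold = threshold), class = "hncn_calls")
}

#' @export
print.hncn_calls <- function(x, ...) {
  cat("hncn_calls:", nrow(x$calls), "SNPs x", ncol(x$calls), "samples;",
      sprintf("%.1f%% called HNCN (threshold %.4f)\n",
              100 * mean(x$calls[x$informative]), x$threshold))
  invisible(x)
}
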