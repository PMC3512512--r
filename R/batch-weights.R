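#' Select the SNP set used for weight estimation
#'
#' Ranks SNP probes by how many samples are normal there (descending) and
#' returns the top \code{size}; the weights are anchored on loci where as
#' many samples as possible contribute a normal signal. Ties in the count
#' are broken by a seeded uniform draw so the selection is deterministic
#' for a given seed.
#'
#' @param mask normal mask over all probes (CN probes are ignored).
#' @param annotation a \code{\link{probe_annotation}} matching the mask
#'   rows.
#' @param size maximum number of SNPs to select.
#' @param seed integer seed for tie-breaking.
#' @return list with \code{indices} (row indices into the mask, ordered by
#'   decreasing normal count) and \code{n_normal} (the per-SNP counts).
#' @export
select_snp_set <- function(mask, annotation, size = 10000L, seed = 1L) {
  if (size < 1L) stop("size must be >= 1")
  if (all(mask == 0L))
    stop("normal mask is all zero: no normal region to anchor weights")
  snp_rows <- which(annotation$probe_class == "SNP")
  counts <- rowSums(mask[snp_rows, , drop = FALSE] == 1L)
  tie_rng <- .derived_rng(seed)
  jitter <- stats::runif(length(counts))
  .restore_rng(tie_rng)
  o <- order(-counts, jitter)
  keep <- o[seq_len(min(size, length(o)))]
  list(indices = snp_rows[keep], n_normal = counts[keep])
}

# evaluate expr under a temporary, seeded RNG state
.derived_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Reference-filled signals over the selected SNP set
#'
#' Builds the matrix the weight estimation works on: the total signal where
#' the sample is normal at the SNP, and the plain per-SNP reference where
#' it is not. Rows with any nonpositive entry are dropped with a warning
#' (their logarithm would be undefined).
#'
#' @param theta1 total-signal matrix.
#' @param mask normal mask (same shape).
#' @param snp_ref plain-median reference from \code{\link{snp_reference}}.
#' @param snp_set selection from \code{\link{select_snp_set}}.
#' @return numeric matrix (selected SNPs x samples).
#' @export
build_filled_signals <- function(theta1, mask, snp_ref, snp_set) {
  idx <- snp_set$indices
  filled <- theta1[idx, , drop = FALSE]
  ref <- snp_ref$reference[idx]
  not_normal <- mask[idx, , drop = FALSE] != 1L
  filled[not_normal] <- ref[row(filled)[not_normal]]
  bad <- rowSums(filled <= 0) > 0
  if (any(bad)) {
    warning(sum(bad), " SNP(s) with nonpositive filled signal dropped",
            " from the weight-estimation set")
    filled <- filled[!bad, , drop = FALSE]
  }
  filled
}

#' Estimate nonnegative per-sample weights
#'
#' For every sample \eqn{i}, finds weights \eqn{\gamma_{i,k} \ge 0}
#' (\eqn{\gamma_{i,i} = 0}) minimizing
#' \deqn{\| \log\hat\theta_{\cdot,i} - \sum_{k \ne i} \gamma_{i,k}
#'       \log\hat\theta_{\cdot,k} \|_2}
#' by iterated ordinary least squares: solve the unconstrained problem on
#' the active sample set, drop every sample whose coefficient is negative,
#' and repeat until all remaining coefficients are nonnegative. A final
#' optimality check re-admits any dropped sample whose column still
#' correlates positively with the residual (the nonnegative-least-squares
#' stationarity condition), so the returned weights attain the exact
#' constrained optimum rather than a heuristic fixed point. Samples
#' processed in the same hybridization batch end up with larger mutual
#' weights, which is what makes the weighted reference batch-aware.
#'
#' @param filled positive matrix from \code{\link{build_filled_signals}}
#'   (selected SNPs x samples, >= 2 samples).
#' @return I x I nonnegative weight matrix with zero diagonal (class
#'   \code{"weight_matrix"}); row i holds the weights sample i assigns to
#'   the other samples. Attribute \code{objective} stores the attained
#'   residual norms.
#' @export
estimate_weights <- function(filled) {
  I <- ncol(filled)
  if (I < 2L) stop("weight estimation needs at least 2 samples")
  if (any(filled <= 0)) stop("filled signals must be strictly positive")
  L <- log(filled)
  if (any(apply(L, 2L, stats::sd) == 0))
    stop("degenerate (constant) log-signal column; cannot estimate weights")
  gamma <- matrix(0, I, I, dimnames = list(colnames(filled), colnames(filled)))
  objective <- numeric(I)
  for (i in seq_len(I)) {
    b <- L[, i]
    candidates <- setdiff(seq_len(I), i)
    active <- candidates
    coefs <- numeric(0)
    for (outer in seq_len(4L * I)) {
      # inner loop: solve, drop every negative-weight sample, repeat
      for (iter in seq_len(I)) {
        if (length(active) == 0L) { coefs <- numeric(0); break }
        A <- L[, active, drop = FALSE]
        coefs <- stats::lm.fit(A, b)$coefficients
        coefs[is.na(coefs)] <- 0     # rank-deficient columns get weight 0
        if (all(coefs >= 0)) break
        active <- active[coefs >= 0]
      }
      # optimality check: a dropped sample whose column still correlates
      # positively with the residual would re-enter with positive weight
      resid <- b - L[, active, drop = FALSE] %*% coefs
      excluded <- setdiff(candidates, active)
      if (length(excluded) == 0L) break
      grad <- drop(crossprod(L[, excluded, drop = FALSE], resid))
      tol <- 1e-10 * max(abs(b)) * sqrt(length(b))
      if (max(grad) <= tol) break
      active <- c(active, excluded[which.max(grad)])
    }
    gamma[i, active] <- pmax(coefs, 0)
    objective[i] <- sqrt(sum((b - L[, active, drop = FALSE] %*%
                                pmax(coefs, 0))^2))
  }
  structure(gamma, objective = objective,
            class = c("weight_matrix", "matrix"))
}

#' Weighted median
#'
#' The weighted median of values \eqn{x_k} with nonnegative weights
#' \eqn{w_k} minimizes \eqn{\sum_k w_k |x_k - m|}. When the half-weight
#' point falls exactly between two order statistics the midpoint is
#' returned, so equal weights reproduce the ordinary sample median for
#' both odd and even lengths. The result is invariant to rescaling all
#' weights by a positive constant.
#'
#' @param values numeric vector (length >= 1).
#' @param weights nonnegative numeric vector, total weight > 0.
#' @return the weighted median (scalar).
#' @export
weighted_median <- function(values, weights) {
  if (length(values) != length(weights))
    stop("values and weights must have the same length")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) <= 0) stop("total weight must be positive")
  o <- order(values)
  .wmedian_sorted(values[o], weights[o])
}

# weighted median of already-sorted values; weights in the same order
.wmedian_sorted <- function(x, w) {
  w <- w / sum(w)                        # normalize: weight-scale invariance
  cw <- cumsum(w)
  k <- which(cw >= 0.5 - 1e-12)[1L]
  if (abs(cw[k] - 0.5) <= 1e-12 && k < length(x)) {
    # half the weight on each side: midpoint of the adjacent order stats
    nz <- which(w[(k + 1L):length(x)] > 0)[1L]
    return((x[k] + x[k + nz]) / 2)
  }
  x[k]
}

#' Batch-aware per-SNP references by weighted median
#'
#' For every probe j and target sample i, the weighted median of the total
#' signals of the samples normal at j, weighted by sample i's weight row.
#' The reference therefore differs not only per probe but also per sample.
#' When no normal sample at j carries positive weight for i (or none
#' exists at all) the plain masked median is used and the entry is
#' flagged.
#'
#' @param theta1 total-signal matrix (all probes x samples).
#' @param mask normal mask (same shape).
#' @param gamma weight matrix from \code{\link{estimate_weights}}.
#' @return list with \code{reference} (J x I matrix) and \code{fallback}
#'   (logical J x I matrix).
#' @export
weighted_snp_reference <- function(theta1, mask, gamma) {
  I <- ncol(theta1)
  if (!all(dim(gamma) == c(I, I))) stop("gamma must be samples x samples")
  if (any(gamma < 0) || any(diag(gamma) != 0))
    stop("gamma must be nonnegative with zero diagonal")
  plain <- snp_reference(theta1, mask)
  ref <- matrix(0, nrow(theta1), I, dimnames = dimnames(theta1))
  fallback <- matrix(FALSE, nrow(theta1), I, dimnames = dimnames(theta1))
  for (j in seq_len(nrow(theta1))) {
    normal_k <- which(mask[j, ] == 1L)
    if (length(normal_k) == 0L) {
      ref[j, ] <- plain$reference[j]
      fallback[j, ] <- TRUE
      next
    }
    vals <- theta1[j, normal_k]
    o <- order(vals)
    vals_s <- vals[o]
    w_all <- gamma[, normal_k, drop = FALSE][, o, drop = FALSE]
    tot <- rowSums(w_all)
    for (i in seq_len(I)) {
      if (tot[i] <= 0) {
        ref[j, i] <- plain$reference[j]
        fallback[j, i] <- TRUE
      } else {
        ref[j, i] <- .wmedian_sorted(vals_s, w_all[i, ])
      }
    }
  }
  list(reference = ref, fallback = fallback)
}
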