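#' Fit the normality-search scaling to a signal set
#'
#' The main entry point. Runs the whole pipeline on summarized allele
#' signals:
#' \enumerate{
#'   \item level of heterozygosity per SNP and sample
#'     (\code{\link{compute_lh}}) and HNCN calls above
#'     \code{lh_threshold} (\code{\link{call_hncn}});
#'   \item per-sample, per-chromosome segmentation of the binary call
#'     track (\code{\link{build_segment_table}});
#'   \item segment labeling at \code{prop_threshold} and expansion into
#'     the probe-by-sample normal mask, CN probes included
#'     (\code{\link{label_segments}}, \code{\link{build_normal_mask}});
#'   \item optional batch-effect removal: SNP-set selection, nonnegative
#'     weight estimation (\code{\link{estimate_weights}});
#'   \item the two-step scaling to copy numbers
#'     (\code{\link{run_scaling}}).
#' }
#'
#' All randomness (segmentation permutations, tie-breaks) derives from
#' \code{seed}; two fits with identical inputs and seed are identical.
#'
#' @param signals a \code{\link{signal_set}}.
#' @param lh_threshold HNCN call threshold, default
#'   \code{\link{default_lh_threshold}()} = 5/6.
#' @param prop_threshold segment-labeling threshold, default
#'   \code{\link{default_proportion_threshold}()} = 0.135.
#' @param alpha,n_perm,min_width segmentation parameters.
#' @param ber logical: estimate batch weights and use weighted-median
#'   references.
#' @param snp_set_size SNPs used for weight estimation (BER only).
#' @param n_iter scaling iterations (>= 1).
#' @param seed integer master seed.
#' @return An object of class \code{"nsa"}: list with \code{cn} (the
#'   \code{cn_matrix}), \code{segments} (labeled segment table),
#'   \code{mask} (normal mask), \code{lh}, \code{calls}, \code{weights}
#'   (NULL unless \code{ber}), \code{signals} and \code{params}.
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 4, n_chromosomes = 2,
#'                                    snps_per_chr = 150, seed = 7))
#' fit <- nsa(sim$signals, n_perm = 200, seed = 7)
#' fit
#' @export
nsa <- function(signals, lh_threshold = default_lh_threshold(),
                prop_threshold = default_proportion_threshold(),
                alpha = 0.01, n_perm = 1000L, min_width = 5L,
                ber = FALSE, snp_set_size = 10000L, n_iter = 1L,
                seed = 1L) {
  stopifnot(inherits(signals, "signal_set"))
  lh <- compute_lh(signals$theta_a, signals$theta_b)
  calls <- call_hncn(lh, lh_threshold)
  segments <- build_segment_table(calls, signals$annotation, alpha = alpha,
                                  n_perm = n_perm, min_width = min_width,
                                  seed = seed)
  segments <- label_segments(segments, prop_threshold)
  mask <- build_normal_mask(segments, signals$annotation)
  weights <- NULL
  if (ber) {
    theta1 <- total_signal(signals)
    snp_set <- select_snp_set(mask, signals$annotation, size = snp_set_size,
                              seed = seed + 1L)
    plain <- snp_reference(theta1, mask)
    filled <- build_filled_signals(theta1, mask, plain, snp_set)
    weights <- estimate_weights(filled)
  }
  cn <- run_scaling(signals, mask, weights = weights, n_iter = n_iter)
  structure(list(cn = cn, segments = segments, mask = mask, lh = lh,
                 calls = calls, weights = weights, signals = signals,
                 params = list(lh_threshold = lh_threshold,
                               prop_threshold = prop_threshold,
                               alpha = alpha, n_perm = n_perm,
                               min_width = min_width, ber = ber,
                               snp_set_size = snp_set_size,
                               n_iter = n_iter, seed = seed)),
            class = "nsa")
}

#' @export
print.nsa <- function(x, ...) {
  cat("Normality-search copy-number scaling\n")
  cat(sprintf("  %d probes (%d SNP, %d CN) x %d samples\n",
              nrow(x$mask), nrow(x$signals$theta_a),
              nrow(x$signals$theta_cn), ncol(x$mask)))
  cat(sprintf("  normal fraction: mean %.2f (range %.2f-%.2f)\n",
              mean(attr(x$mask, "normal_fraction")),
              min(attr(x$mask, "normal_fraction")),
              max(attr(x$mask, "normal_fraction"))))
  cat(sprintf("  copy numbers: median %.3f, batch-effect removal %s\n",
              stats::median(x$cn$values),
              if (x$params$ber) "on" else "off"))
  invisible(x)
}

#' @export
summary.nsa <- function(object, ...) {
  mask <- object$mask
  segs <- object$segments
  per_sample <- data.frame(
    sample_id = colnames(mask),
    normal_fraction = as.numeric(attr(mask, "normal_fraction")),
    n_segments = as.integer(table(factor(segs$sample_id,
                                         levels = colnames(mask)))),
    median_cn = apply(object$cn$values, 2L, stats::median),
    sample_reference = object$cn$references$sample,
    row.names = NULL)
  out <- list(per_sample = per_sample,
              n_normal_segments = sum(segs$normal_label == 1L),
              n_segments = nrow(segs),
              probe_fallbacks = sum(object$cn$flags$probe_fallback),
              iteration_delta = object$cn$iteration_delta,
              params = object$params)
  class(out) <- "summary.nsa"
  out
}

#' @export
print.summary.nsa <- function(x, ...) {
  cat(sprintf("Segments: %d (%d labeled normal); probe fallbacks: %d\n",
              x$n_segments, x$n_normal_segments, x$probe_fallbacks))
  if (length(x$iteration_delta))
    cat("Mean |copy-number change| per extra iteration:",
        paste(signif(x$iteration_delta, 3), collapse = ", "), "\n")
  cat("Per-sample summary:\n")
  print(x$per_sample, digits = 4)
  invisible(x)
}

#' Extract references from a fit
#'
#' The estimated scale factors: the per-sample references (near 2 on
#' calibrated data) and, as an attribute, the per-SNP references.
#'
#' @param object an \code{nsa} fit.
#' @param ... unused.
#' @return named numeric vector of per-sample references with attribute
#'   \code{snp_reference}.
#' @export
coef.nsa <- function(object, ...) {
  structure(object$cn$references$sample,
            snp_reference = object$cn$references$snp)
}

#' @export
fitted.nsa <- function(object, ...) object$cn$values

#' Residual copy number in normal regions
#'
#' Deviation of the copy-number estimates from 2 at the probes labeled
#' normal (NA elsewhere): on well-calibrated data these residuals are
#' centered at zero.
#'
#' @param object an \code{nsa} fit.
#' @param ... unused.
#' @return matrix of residuals, NA outside the normal mask.
#' @export
residuals.nsa <- function(object, ...) {
  r <- object$cn$values - 2
  r[object$mask != 1L] <- NA_real_
  r
}

#' Plot LH track and segmentation for one sample and chromosome
#'
#' Shows the per-SNP level of heterozygosity, the segment-wise HNCN
#' proportions (step line) and the labeling threshold; normal segments
#' are shaded.
#'
#' @param x an \code{nsa} fit.
#' @param sample sample id or index.
#' @param chromosome chromosome name; default the first.
#' @param ... passed to \code{plot}.
#' @export
plot.nsa <- function(x, sample = 1L, chromosome = NULL, ...) {
  ann <- x$signals$annotation
  snp <- ann[ann$probe_class == "SNP", , drop = FALSE]
  if (is.null(chromosome)) chromosome <- snp$chromosome[1L]
  if (is.numeric(sample)) sample <- colnames(x$mask)[sample]
  sel <- snp$chromosome == chromosome
  pos <- snp$position[sel] / 1e6
  graphics::plot(pos, x$lh[sel, sample], pch = ".", col = "grey40",
                 xlab = sprintf("%s position (Mb)", chromosome),
                 ylab = "level of heterozygosity", ylim = c(0, 1.05), ...)
  segs <- x$segments[x$segments$sample_id == sample &
                       x$segments$chromosome == chromosome, , drop = FALSE]
  for (k in seq_len(nrow(segs))) {
    if (segs$normal_label[k] == 1L)
      graphics::rect(segs$start_bp[k] / 1e6, 0, segs$end_bp[k] / 1e6, 1.05,
                     col = grDevices::adjustcolor("steelblue", 0.15),
                     border = NA)
    graphics::segments(segs$start_bp[k] / 1e6, segs$hncn_proportion[k],
                       segs$end_bp[k] / 1e6, segs$hncn_proportion[k],
                       lwd = 3, col = "grey20")
  }
  graphics::abline(h = x$params$prop_threshold, lty = 2, col = "firebrick")
  invisible(x)
}
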