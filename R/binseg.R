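#' Segment a binary HNCN track with circular binary segmentation
#'
#' Recursive circular binary segmentation (CBS) on a 0/1 vector of
#' balanced-heterozygote calls. For the current stretch every circular arc
#' is scored with the standardized difference in HNCN proportion between
#' the arc and its complement; the maximizing arc is accepted as a split
#' when its permutation p-value (label permutations of the stretch) falls
#' below \code{alpha}, and segmentation recurses into the resulting pieces.
#' Non-informative markers (missing LH) carry no evidence: they are skipped
#' by the statistic but remain inside segments for coverage accounting.
#'
#' Ties in the maximal statistic are broken deterministically (smallest arc
#' start, then smallest arc length), and the permutation stream is seeded,
#' so results are reproducible.
#'
#' @param calls integer vector of 0/1 HNCN calls (one per marker, in
#'   genomic order).
#' @param informative logical vector, FALSE for markers whose LH was
#'   missing; default all TRUE.
#' @param alpha per-split significance level in (0, 1).
#' @param n_perm number of label permutations per candidate split.
#' @param min_width minimum number of informative markers per segment.
#' @param seed integer seed for the permutation generator.
#' @return Integer vector of breakpoints as 0-based marker indices into the
#'   full \code{calls} vector: a breakpoint \code{b} separates markers
#'   \code{[.., b-1]} from \code{[b, ..]}. Sorted, possibly empty.
#' @seealso \code{\link{best_single_split_oracle}} for an exhaustive
#'   single-split reference implementation used in tests.
#' @export
segment_binary <- function(calls, informative = NULL, alpha = 0.01,
                           n_perm = 1000L, min_width = 5L, seed = 1L) {
  if (min_width < 1L) stop("min_width must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  calls <- as.integer(calls)
  if (is.null(informative)) informative <- rep(TRUE, length(calls))
  if (length(informative) != length(calls))
    stop("calls and informative must have the same length")
  idx <- which(informative)            # informative-marker index -> full index
  if (length(idx) < 2L * min_width) return(integer(0))
  res <- .cbs_binary_cpp(calls[idx], alpha, as.integer(n_perm),
                         as.integer(min_width), as.integer(seed))
  bp_inf <- res$breakpoints            # 0-based, in informative space
  # a breakpoint before informative marker k maps to the full index of that
  # marker, so non-informative markers stay attached to the left segment
  sort(idx[bp_inf + 1L] - 1L)
}

#' Exhaustive single-split oracle
#'
#' Scans every circular arc of a 0/1 vector (restricted to informative
#' markers) in O(n^2) and returns the maximal standardized
#' proportion-difference statistic together with the maximizing arc. Ties
#' are broken exactly as in \code{\link{segment_binary}} (smallest start,
#' then smallest length). Intended as an independent reference for testing
#' the segmentation core; it applies no permutation test and no minimum
#' width.
#'
#' @param calls integer 0/1 vector.
#' @param informative logical vector; default all TRUE.
#' @return list with \code{stat} (the maximal statistic; 0 for constant
#'   input) and \code{arc} = \code{c(start, end)}, the maximizing arc
#'   \code{[start, end)} as 0-based indices into the informative
#'   subsequence (\code{NA} for constant input).
#' @export
best_single_split_oracle <- function(calls, informative = NULL) {
  calls <- as.integer(calls)
  if (is.null(informative)) informative <- rep(TRUE, length(calls))
  x <- calls[informative]
  n <- length(x)
  s <- sum(x)
  if (n < 2L || s == 0L || s == n)
    return(list(stat = 0, arc = c(NA_integer_, NA_integer_)))
  C <- c(0L, cumsum(x))
  p <- s / n
  best <- list(stat = 0, arc = c(NA_integer_, NA_integer_))
  for (i in 0:(n - 1L)) {
    for (l in 1:(n - i)) {
      if (i == 0L && l == n) next
      d <- C[i + l + 1L] - C[i + 1L]
      z <- abs(d - l * s / n) / sqrt(p * (1 - p) * l * (n - l) / n)
      if (z > best$stat) {
        best$stat <- z
        best$arc <- c(i, i + l)
      }
    }
  }
  best
}

#' Build a per-sample, per-chromosome segment table
#'
#' Runs \code{\link{segment_binary}} independently for every sample and
#' chromosome of an HNCN call matrix and assembles the resulting partition
#' into a segment table with marker counts, bp bounds (positions of the
#' first and last marker of each segment, 1-based inclusive) and the
#' proportion of HNCN calls among informative markers. Chromosomes with
#' fewer markers than \code{min_width} yield a single segment flagged in
#' the \code{flagged} column (with a warning).
#'
#' @param calls an \code{hncn_calls} object (see \code{\link{call_hncn}}).
#' @param annotation a \code{\link{probe_annotation}}; only its SNP probes
#'   are used and they must match the rows of \code{calls}.
#' @param alpha,n_perm,min_width,seed segmentation parameters, see
#'   \code{\link{segment_binary}}.
#' @return A \code{data.frame} (class \code{"segment_table"}) with columns
#'   \code{sample_id}, \code{chromosome}, \code{start_marker} (0-based),
#'   \code{end_marker} (exclusive), \code{start_bp}, \code{end_bp},
#'   \code{n_markers}, \code{n_informative}, \code{hncn_proportion},
#'   \code{flagged}. Marker indices refer to SNP probes of the chromosome
#'   in annotation order.
#' @export
build_segment_table <- function(calls, annotation, alpha = 0.01,
                                n_perm = 1000L, min_width = 5L, seed = 1L) {
  stopifnot(inherits(calls, "hncn_calls"))
  snp <- annotation[annotation$probe_class == "SNP", , drop = FALSE]
  if (!identical(rownames(calls$calls), snp$probe_id))
    stop("call matrix rows do not match the annotation's SNP probes")
  samples <- colnames(calls$calls)
  chroms <- unique(snp$chromosome)
  rows <- vector("list", length(samples) * length(chroms))
  r <- 0L
  for (ci in seq_along(chroms)) {
    in_chr <- which(snp$chromosome == chroms[ci])
    pos <- snp$position[in_chr]
    for (si in seq_along(samples)) {
      v <- calls$calls[in_chr, si]
      inf <- calls$informative[in_chr, si]
      flag <- FALSE
      if (length(in_chr) < min_width || sum(inf) < 2L * min_width) {
        bps <- integer(0)
        flag <- length(in_chr) < min_width
        if (flag)
          warning("chromosome ", chroms[ci], " has fewer than min_width (",
                  min_width, ") markers; left as a single flagged segment")
      } else {
        sub_seed <- as.integer((as.numeric(seed) * 1009 + si * 131 + ci * 7) %%
                                 .Machine$integer.max)
        bps <- segment_binary(v, inf, alpha = alpha, n_perm = n_perm,
                              min_width = min_width, seed = sub_seed)
      }
      starts <- c(0L, bps)
      ends <- c(bps, length(in_chr))
      n_inf <- vapply(seq_along(starts), function(k)
        sum(inf[(starts[k] + 1L):ends[k]]), integer(1L))
      prop <- vapply(seq_along(starts), function(k) {
        sel <- (starts[k] + 1L):ends[k]
        if (n_inf[k] == 0L) NA_real_ else mean(v[sel][inf[sel]])
      }, numeric(1L))
      r <- r + 1L
      rows[[r]] <- data.frame(
        sample_id = samples[si], chromosome = chroms[ci],
        start_marker = starts, end_marker = ends,
        start_bp = pos[starts + 1L], end_bp = pos[ends],
        n_markers = ends - starts, n_informative = n_inf,
        hncn_proportion = prop, flagged = flag,
        stringsAsFactors = FALSE)
    }
  }
  if (r == 0L) {
    out <- data.frame(sample_id = character(0), chromosome = character(0),
                      start_marker = integer(0), end_marker = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_markers = integer(0), n_informative = integer(0),
                      hncn_proportion = numeric(0), flagged = logical(0))
  } else {
    out <- do.call(rbind, rows[seq_len(r)])
  }
  rownames(out) <- NULL
  class(out) <- c("segment_table", "data.frame")
  out
}
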