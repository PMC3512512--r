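# Expected fraction of heterozygous SNPs per sample in a diploid genome
# (HapMap-like populations); the segment-labeling default derives from it.
EXPECTED_HET <- 0.27

#' Default HNCN-proportion threshold for labeling segments normal
#'
#' In a copy-number-neutral, LOH-free region the proportion of SNPs called
#' HNCN should approach the population heterozygosity (about 27% per
#' sample), while in an aberrated region it should approach 0. The default
#' labeling threshold is the midpoint of those two expectations,
#' \code{EXPECTED_HET / 2 = 0.135}, derived from the package's
#' heterozygosity constant rather than stated as a second literal.
#'
#' @return the scalar 0.135.
#' @export
default_proportion_threshold <- function() EXPECTED_HET / 2

#' Label segments as normal or aberrated
#'
#' A segment is labeled normal (\code{normal_label = 1}) when its HNCN
#' proportion is at least \code{prop_threshold}; segments with no
#' informative marker get label 0 and are flagged. The comparison is
#' \code{>=}, so a proportion exactly at the threshold counts as normal.
#'
#' @param segments a segment table from \code{\link{build_segment_table}}.
#' @param prop_threshold labeling threshold; default
#'   \code{\link{default_proportion_threshold}()}.
#' @return the segment table with columns \code{normal_label} (0/1) and
#'   updated \code{flagged}.
#' @export
label_segments <- function(segments, prop_threshold = default_proportion_threshold()) {
  segments <- as.data.frame(segments)
  uninf <- is.na(segments$hncn_proportion) | segments$n_informative == 0L
  segments$normal_label <- as.integer(!uninf &
                                        segments$hncn_proportion >= prop_threshold)
  segments$flagged <- segments$flagged | uninf
  class(segments) <- c("segment_table", "data.frame")
  segments
}

#' Build the probe-by-sample normal-status mask
#'
#' Expands labeled segments into a binary matrix over all probes (SNP and
#' CN) by sample. Each SNP probe inherits the label of its containing
#' segment. CN probes, which do not take part in segmentation, inherit the
#' label of the SNP-defined segment whose bp interval contains their
#' position; CN probes before the first / after the last SNP of a
#' chromosome inherit the nearest segment's label. CN probes on a
#' chromosome without SNP probes are labeled 0 with a warning.
#'
#' @param labeled a labeled segment table from \code{\link{label_segments}}.
#' @param annotation a \code{\link{probe_annotation}} covering all probes.
#' @return An object of class \code{"normal_mask"}: binary matrix (probes
#'   in annotation order x samples) with attribute \code{normal_fraction}
#'   (per-sample fraction of probes labeled normal).
#' @export
build_normal_mask <- function(labeled, annotation) {
  if (!"normal_label" %in% names(labeled))
    stop("segments must be labeled first (see label_segments)")
  samples <- unique(labeled$sample_id)
  mask <- matrix(0L, nrow = nrow(annotation), ncol = length(samples),
                 dimnames = list(annotation$probe_id, samples))
  is_snp <- annotation$probe_class == "SNP"
  warned <- character(0)
  for (chr in unique(annotation$chromosome)) {
    in_chr <- annotation$chromosome == chr
    snp_rows <- which(in_chr & is_snp)
    cn_rows <- which(in_chr & !is_snp)
    segs_chr <- labeled[labeled$chromosome == chr, , drop = FALSE]
    if (length(snp_rows) == 0L || nrow(segs_chr) == 0L) {
      if (length(cn_rows)) warned <- c(warned, chr)
      next
    }
    cn_pos <- annotation$position[cn_rows]
    for (si in seq_along(samples)) {
      segs <- segs_chr[segs_chr$sample_id == samples[si], , drop = FALSE]
      segs <- segs[order(segs$start_marker), , drop = FALSE]
      if (nrow(segs) == 0L) next
      # SNP probes: constant within each segment by construction
      for (k in seq_len(nrow(segs)))
        mask[snp_rows[(segs$start_marker[k] + 1L):segs$end_marker[k]], si] <-
          segs$normal_label[k]
      if (length(cn_rows)) {
        # containment by bp interval, nearest segment outside SNP coverage
        seg_of <- findInterval(cn_pos, segs$start_bp)
        seg_of[seg_of == 0L] <- 1L                   # before first SNP
        past <- cn_pos > segs$end_bp[seg_of]         # gaps / after last SNP
        if (any(past)) {
          d_left <- cn_pos[past] - segs$end_bp[seg_of[past]]
          nxt <- pmin(seg_of[past] + 1L, nrow(segs))
          d_right <- abs(segs$start_bp[nxt] - cn_pos[past])
          seg_of[past] <- ifelse(d_right < d_left, nxt, seg_of[past])
        }
        mask[cn_rows, si] <- segs$normal_label[seg_of]
      }
    }
  }
  if (length(warned))
    warning("CN probes on chromosome(s) without SNP probes labeled 0: ",
            paste(unique(warned), collapse = ", "))
  frac <- colMeans(mask)
  if (any(frac == 0))
    warning("sample(s) with no normal probes (every segment aberrated): ",
            paste(samples[frac == 0], collapse = ", "))
  structure(mask, normal_fraction = frac, class = c("normal_mask", "matrix"))
}
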