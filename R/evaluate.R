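#' Empirical ROC curve
#'
#' Sweeps every distinct value as a threshold (values strictly above the
#' threshold are called positive; the higher-copy-number side is the
#' positive class), groups ties into a single step and returns the monotone
#' ROC curve with its trapezoidal area.
#'
#' @param values numeric vector of scores (e.g. copy-number estimates).
#' @param labels binary vector (1 = positive class), same length.
#' @return object of class \code{"roc_result"}: list with
#'   \code{thresholds}, \code{fpr}, \code{tpr} (including the (0,0) and
#'   (1,1) endpoints) and \code{auc}.
#' @export
roc_curve <- function(values, labels) {
  labels <- as.integer(labels)
  if (length(values) != length(labels))
    stop("values and labels must have the same length")
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  o <- order(values, decreasing = TRUE)
  v <- values[o]
  y <- labels[o]
  P <- sum(y == 1L)
  N <- sum(y == 0L)
  last <- cumsum(rep(1L, length(v)))[!duplicated(v, fromLast = TRUE)]
  # after lowering the threshold just below each distinct value, everything
  # above it is called positive
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = c(Inf, unique(v)), fpr = fpr, tpr = tpr,
                 auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Parse or build a genomic region
#'
#' @param chromosome chromosome name (opaque string).
#' @param start_bp,end_bp 1-based inclusive bounds.
#' @return a list of class \code{"genome_region"}.
#' @export
genome_region <- function(chromosome, start_bp, end_bp) {
  if (end_bp < start_bp) stop("end_bp must be >= start_bp")
  structure(list(chromosome = as.character(chromosome),
                 start_bp = as.numeric(start_bp),
                 end_bp = as.numeric(end_bp)), class = "genome_region")
}

.in_region <- function(annotation, region) {
  annotation$chromosome == region$chromosome &
    annotation$position >= region$start_bp &
    annotation$position <= region$end_bp
}

#' ROC for a copy-number change between two regions
#'
#' Labels the probes of \code{region_b} positive (the higher-copy-number
#' side) and those of \code{region_a} negative, drops probes inside the
#' safety zone around the change point (where the exact breakpoint
#' position is uncertain), and evaluates the ROC of the sample's
#' copy-number estimates.
#'
#' @param cn copy-number matrix (or \code{cn_matrix} object).
#' @param annotation a \code{\link{probe_annotation}} matching the rows.
#' @param sample sample id (column name) or index.
#' @param region_a,region_b \code{\link{genome_region}}s: lower- and
#'   higher-copy-number side.
#' @param safety optional \code{\link{genome_region}} excluded from the
#'   analysis.
#' @return a \code{\link{roc_curve}} result.
#' @export
region_roc <- function(cn, annotation, sample, region_a, region_b,
                       safety = NULL) {
  m <- if (inherits(cn, "cn_matrix")) cn$values else as.matrix(cn)
  in_a <- .in_region(annotation, region_a)
  in_b <- .in_region(annotation, region_b)
  if (!is.null(safety)) {
    excl <- .in_region(annotation, safety)
    in_a <- in_a & !excl
    in_b <- in_b & !excl
  }
  if (any(in_a & in_b)) stop("regions overlap after safety exclusion")
  if (!any(in_a) || !any(in_b))
    stop("a region is empty after safety exclusion")
  sel <- in_a | in_b
  roc_curve(m[annotation$probe_id[sel], sample],
            as.integer(in_b[sel]))
}

#' All-tumor-median reference (MTS baseline)
#'
#' The per-probe median over every sample, with no normality masking -
#' the classic median-of-tumoral-samples reference that a recurrent
#' aberration present in more than half the samples will bias.
#'
#' @param theta1 total-signal matrix.
#' @return length-J reference vector.
#' @export
mts_reference <- function(theta1) {
  ref <- apply(theta1, 1L, stats::median)
  names(ref) <- rownames(theta1)
  ref
}

#' Control-sample-median reference (MCS baseline)
#'
#' The per-probe median over designated control columns.
#'
#' @param theta1 total-signal matrix.
#' @param control_ids sample ids (column names) of the controls.
#' @return length-J reference vector.
#' @export
mcs_reference <- function(theta1, control_ids) {
  missing <- setdiff(control_ids, colnames(theta1))
  if (length(missing))
    stop("unknown control sample id(s): ", paste(missing, collapse = ", "))
  if (length(control_ids) < 1L) stop("need at least one control sample")
  ref <- apply(theta1[, control_ids, drop = FALSE], 1L, stats::median)
  names(ref) <- rownames(theta1)
  ref
}

#' Scale a signal set with a baseline (unmasked) reference
#'
#' Convenience comparison mode: runs the same two-step scaling as
#' \code{\link{run_scaling}} but with every entry treated as normal, so
#' the per-SNP reference is the all-sample median (MTS) or a control-set
#' median (MCS) and the per-sample reference is the genome-wide median.
#'
#' @param signals a \code{\link{signal_set}}.
#' @param method \code{"mts"} or \code{"mcs"}.
#' @param control_ids control sample ids (MCS only).
#' @return a \code{cn_matrix} object.
#' @export
scale_baseline <- function(signals, method = c("mts", "mcs"),
                           control_ids = NULL) {
  method <- match.arg(method)
  theta1 <- total_signal(signals)
  ref <- switch(method, mts = mts_reference(theta1),
                mcs = mcs_reference(theta1, control_ids))
  theta2 <- scale_by_snp(theta1, ref)
  samp <- apply(theta2, 2L, stats::median)
  values <- scale_by_sample(theta2, samp)
  structure(list(values = values,
                 flags = list(probe_fallback = logical(nrow(theta1)),
                              sample_fallback = logical(ncol(theta1))),
                 references = list(snp = ref, sample = samp),
                 iteration_delta = numeric(0)),
            class = "cn_matrix")
}
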