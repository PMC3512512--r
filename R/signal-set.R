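#' Probe annotation table
#'
#' Validates and canonically orders a probe annotation table. Probes are
#' sorted by (chromosome, position, probe_id) with a locale-independent
#' (radix) ordering, so the probe order used throughout the package is a
#' deterministic function of the annotation alone. Chromosome names are
#' opaque strings: \code{"chr8"} and \code{"8"} are different chromosomes
#' and no sex-chromosome special-casing is applied.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chromosome character vector of chromosome names.
#' @param position integer vector of 1-based bp positions (>= 1).
#' @param probe_class character vector, each element \code{"SNP"} or
#'   \code{"CN"} (non-polymorphic total-copy probe).
#' @return A \code{data.frame} with the four columns above, sorted
#'   canonically, of class \code{c("probe_annotation", "data.frame")}.
#' @export
probe_annotation <- function(probe_id, chromosome, position, probe_class) {
  probe_id <- as.character(probe_id)
  n <- length(probe_id)
  recycle1 <- function(x) if (length(x) == 1L) rep(x, n) else x
  chromosome <- as.character(recycle1(chromosome))
  position <- as.integer(position)
  probe_class <- as.character(recycle1(probe_class))
  if (length(chromosome) != n || length(position) != n || length(probe_class) != n)
    stop("annotation columns must have equal length")
  if (anyDuplicated(probe_id))
    stop("duplicated probe_id in annotation: ",
         paste(utils::head(probe_id[duplicated(probe_id)], 3L), collapse = ", "))
  if (any(is.na(position)) || any(position < 1L))
    stop("positions must be integers >= 1")
  bad <- !probe_class %in% c("SNP", "CN")
  if (any(bad))
    stop("probe_class must be 'SNP' or 'CN' (offending probe: ",
         probe_id[which(bad)[1L]], ")")
  o <- order(chromosome, position, probe_id, method = "radix")
  ann <- data.frame(probe_id = probe_id[o], chromosome = chromosome[o],
                    position = position[o], probe_class = probe_class[o],
                    stringsAsFactors = FALSE)
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Container for summarized allele signals
#'
#' Bundles the allele-specific signal matrices \code{theta_a} and
#' \code{theta_b} for SNP probes, an optional total-signal matrix
#' \code{theta_cn} for non-polymorphic CN probes, and the probe annotation.
#' Signal rows are stored in the canonical annotation order (restricted to
#' the corresponding probe class); columns follow \code{sample_ids}.
#'
#' @param theta_a,theta_b nonnegative numeric matrices (SNP probes x
#'   samples) with probe-id rownames and sample-id colnames.
#' @param annotation a \code{\link{probe_annotation}} covering every probe.
#' @param theta_cn optional nonnegative matrix for CN probes (same samples).
#' @return An object of class \code{"signal_set"}: a list with elements
#'   \code{theta_a}, \code{theta_b}, \code{theta_cn}, \code{annotation},
#'   \code{sample_ids}.
#' @export
signal_set <- function(theta_a, theta_b, annotation, theta_cn = NULL) {
  if (!inherits(annotation, "probe_annotation"))
    annotation <- probe_annotation(annotation$probe_id, annotation$chromosome,
                                   annotation$position, annotation$probe_class)
  theta_a <- as.matrix(theta_a)
  theta_b <- as.matrix(theta_b)
  if (is.null(rownames(theta_a)) || is.null(colnames(theta_a)))
    stop("theta_a must carry probe-id rownames and sample-id colnames")
  sample_ids <- colnames(theta_a)
  theta_b <- .reconcile_matrix(theta_b, rownames(theta_a), sample_ids, "theta_b")
  .check_signal_values(theta_a, "theta_a")
  .check_signal_values(theta_b, "theta_b")
  snp_ids <- annotation$probe_id[annotation$probe_class == "SNP"]
  cn_ids <- annotation$probe_id[annotation$probe_class == "CN"]
  missing_ann <- setdiff(rownames(theta_a), annotation$probe_id)
  if (length(missing_ann))
    stop("probe(s) present in signals but absent from annotation: ",
         paste(utils::head(missing_ann, 3L), collapse = ", "))
  if (!setequal(rownames(theta_a), snp_ids))
    stop("SNP signal rows do not match the SNP probes in the annotation")
  theta_a <- theta_a[snp_ids, , drop = FALSE]
  theta_b <- theta_b[snp_ids, , drop = FALSE]
  if (!is.null(theta_cn) && nrow(as.matrix(theta_cn)) > 0L) {
    theta_cn <- as.matrix(theta_cn)
    theta_cn <- .reconcile_matrix(theta_cn, NULL, sample_ids, "theta_cn")
    if (!setequal(rownames(theta_cn), cn_ids))
      stop("CN signal rows do not match the CN probes in the annotation")
    .check_signal_values(theta_cn, "theta_cn")
    theta_cn <- theta_cn[cn_ids, , drop = FALSE]
  } else {
    if (length(cn_ids))
      stop("annotation declares CN probes but no theta_cn matrix was given")
    theta_cn <- matrix(numeric(0), nrow = 0L, ncol = length(sample_ids),
                       dimnames = list(NULL, sample_ids))
  }
  structure(list(theta_a = theta_a, theta_b = theta_b, theta_cn = theta_cn,
                 annotation = annotation, sample_ids = sample_ids),
            class = "signal_set")
}

# column/row reconciliation by id; never by position
.reconcile_matrix <- function(m, row_ids, sample_ids, what) {
  if (is.null(colnames(m)))
    stop(what, " must carry sample-id colnames")
  if (!setequal(colnames(m), sample_ids))
    stop("sample ids of ", what, " do not match theta_a (missing: ",
         paste(utils::head(setdiff(sample_ids, colnames(m)), 3L), collapse = ", "), ")")
  m <- m[, sample_ids, drop = FALSE]
  if (!is.null(row_ids)) {
    if (is.null(rownames(m)) || !setequal(rownames(m), row_ids))
      stop("probe ids of ", what, " do not match theta_a")
    m <- m[row_ids, , drop = FALSE]
  }
  m
}

.check_signal_values <- function(m, what) {
  if (!is.numeric(m)) stop(what, " contains non-numeric entries")
  if (any(!is.finite(m))) stop(what, " contains non-finite entries")
  if (any(m < 0)) stop(what, " contains negative entries")
  invisible(TRUE)
}

#' @export
print.signal_set <- function(x, ...) {
  cat("signal_set:", nrow(x$theta_a), "SNP probes,", nrow(x$theta_cn),
      "CN probes,", length(x$sample_ids), "samples,",
      length(unique(x$annotation$chromosome)), "chromosomes\n")
  invisible(x)
}

#' Number of probes / samples in a signal set
#' @param signals a \code{signal_set}.
#' @return integer counts.
#' @keywords internal
n_probes <- function(signals) nrow(signals$theta_a) + nrow(signals$theta_cn)

#' Read a signal set from tab-separated files
#'
#' Reads allele-signal matrices and the probe annotation from TSV files
#' (first column probe id, header sample ids, "." decimal, UTF-8). Samples
#' are matched across files by id, never by column position; probe rows are
#' re-ordered to the canonical annotation order.
#'
#' @param theta_a_path,theta_b_path paths to the allele signal TSVs.
#' @param annotation_path path to the annotation TSV with columns
#'   \code{probe_id}, \code{chromosome}, \code{position}, \code{probe_class}.
#' @param theta_cn_path optional path to the CN-probe total signal TSV.
#' @return A \code{\link{signal_set}}.
#' @export
read_signal_set <- function(theta_a_path, theta_b_path, annotation_path,
                            theta_cn_path = NULL) {
  ann_df <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome", "position", "probe_class")
  if (!all(need %in% names(ann_df)))
    stop("annotation file ", annotation_path, " lacks columns: ",
         paste(setdiff(need, names(ann_df)), collapse = ", "))
  ann <- probe_annotation(ann_df$probe_id, ann_df$chromosome,
                          ann_df$position, ann_df$probe_class)
  ta <- .read_matrix_tsv(theta_a_path)
  tb <- .read_matrix_tsv(theta_b_path)
  tcn <- if (!is.null(theta_cn_path)) .read_matrix_tsv(theta_cn_path) else NULL
  signal_set(ta, tb, ann, tcn)
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("matrix file ", path, " needs probe_id + >=1 sample column")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  rownames(m) <- ids
  m
}

.write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), format(m, digits = 6, trim = TRUE,
                                       scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Write a copy-number matrix as TSV
#'
#' Layout mirrors the input signal files (probe-id first column, sample ids
#' in the header); values are written with 6 significant digits so a
#' read-back reproduces them to formatting precision.
#'
#' @param cn a \code{cn_matrix} (see \code{\link{run_scaling}}) or a plain
#'   numeric matrix with dimnames.
#' @param path output file path.
#' @export
write_cn_matrix <- function(cn, path) {
  m <- if (inherits(cn, "cn_matrix")) cn$values else as.matrix(cn)
  if (nrow(m) > 0 && any(!is.finite(m)))
    stop("copy-number matrix contains non-finite values; refusing to write")
  if (nrow(m) == 0L) {
    writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), path)
    return(invisible(path))
  }
  .write_matrix_tsv(m, path)
  invisible(path)
}

#' Read a matrix TSV written by \code{\link{write_cn_matrix}}
#' @param path file path.
#' @return numeric matrix with probe-id rownames.
#' @export
read_cn_matrix <- function(path) .read_matrix_tsv(path)

.seg_columns <- c("sample", "chromosome", "start_bp", "end_bp",
                  "num_markers", "hncn_proportion", "normal_label")

#' Write a segment table in SEG format
#'
#' Serializes a segmentation (see \code{\link{build_segment_table}}) as a
#' SEG-style TSV with columns \code{sample}, \code{chromosome},
#' \code{start_bp}, \code{end_bp}, \code{num_markers},
#' \code{hncn_proportion}, \code{normal_label}; coordinates are 1-based
#' inclusive bp. Errors if segments overlap within a sample/chromosome.
#'
#' @param segments a segment table \code{data.frame}.
#' @param path output file path.
#' @export
write_segments_seg <- function(segments, path) {
  segments <- as.data.frame(segments)
  if (!"normal_label" %in% names(segments)) segments$normal_label <- NA_integer_
  for (grp in split(segments, list(segments$sample_id, segments$chromosome),
                    drop = TRUE)) {
    o <- order(grp$start_bp)
    if (nrow(grp) > 1L && any(grp$start_bp[o][-1L] <= grp$end_bp[o][-nrow(grp)]))
      stop("overlapping segments for sample ", grp$sample_id[1L],
           " chromosome ", grp$chromosome[1L])
  }
  out <- data.frame(sample = segments$sample_id,
                    chromosome = segments$chromosome,
                    start_bp = segments$start_bp, end_bp = segments$end_bp,
                    num_markers = segments$n_markers,
                    hncn_proportion = signif(segments$hncn_proportion, 6),
                    normal_label = segments$normal_label,
                    stringsAsFactors = FALSE)
  o <- order(out$sample, out$chromosome, out$start_bp, method = "radix")
  utils::write.table(out[o, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a SEG file written by \code{\link{write_segments_seg}}
#' @param path file path.
#' @return \code{data.frame} with the SEG columns.
#' @export
read_segments_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(.seg_columns %in% names(df)))
    stop("not a SEG file written by this package: ", path)
  df
}
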