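#' Row-normalise an expression matrix to percent expression
#'
#' Divides each gene's normalised read count at every timepoint by the
#' gene's total over all timepoints, so each retained row sums to 1.
#' Zero-sum rows cannot be normalised; they are dropped and reported in the
#' `excluded` attribute rather than divided.
#'
#' @param mat Numeric matrix, genes in rows (rownames = gene ids), hourly
#'   timepoints in columns.
#' @return The row-normalised matrix, with an attribute `excluded` holding
#'   the ids of zero-sum genes.
#' @export
percent_expression <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("expression values must be non-negative")
  rs <- rowSums(mat)
  excluded <- rownames(mat)[rs == 0]
  out <- mat[rs > 0, , drop = FALSE] / rs[rs > 0]
  attr(out, "excluded") <- excluded
  out
}

#' Collapse replicate expression matrices
#'
#' Technical replicates are summed; biological replicates are averaged.
#' Pass a list of gene x timepoint matrices (identical dimnames) and a
#' grouping that assigns each matrix to a biological replicate; matrices
#' sharing a group are technical replicates of each other.
#'
#' @param mats List of numeric matrices with identical dimnames.
#' @param biological Vector (one entry per matrix) naming the biological
#'   replicate each matrix belongs to. Default: all matrices are technical
#'   replicates of a single biological sample.
#' @return One collapsed matrix.
#' @export
collapse_replicates <- function(mats, biological = rep(1, length(mats))) {
  stopifnot(is.list(mats), length(mats) >= 1L,
            length(biological) == length(mats))
  dn <- dimnames(mats[[1]])
  for (m in mats)
    if (!identical(dimnames(m), dn)) stop("matrices must share dimnames")
  groups <- split(mats, biological)
  sums <- lapply(groups, function(g) Reduce(`+`, g))
  Reduce(`+`, sums) / length(sums)
}

#' Assign genes to cell-cycle peak bins by MAD outliers
#'
#' Implements the time-course peak-binning procedure: genes with a low mean
#' raw count are excluded; remaining profiles are normalised to percent
#' expression; timepoints whose percent expression exceeds the profile
#' median by more than `mad_factor` median absolute deviations are outliers;
#' a gene with at least one outlier is binned at the timepoint of its
#' highest outlier (earliest timepoint on exact ties), genes without
#' outliers are excluded.
#'
#' The MAD is unscaled by default (literally "1.5 median absolute
#' deviations"); set `scaled_mad = TRUE` for the 1.4826 normal-consistency
#' constant used by [stats::mad()]'s default.
#'
#' @param mat Numeric matrix of normalised read counts, genes in rows,
#'   hourly timepoints in columns (column names label the bins).
#' @param mad_factor Outlier threshold in MAD units above the median.
#' @param min_mean_count Genes with a mean raw count below this are
#'   excluded before binning.
#' @param scaled_mad Use the 1.4826 consistency constant.
#' @return Data frame with one row per gene: `gene_id`, `status`
#'   (`"binned"`, `"excluded_low_count"` or `"excluded_no_outlier"`),
#'   `peak_bin` (timepoint label, `NA` unless binned), `profile_median`,
#'   `profile_mad` and `peak_value` (percent-expression scale).
#' @export
detect_peak_bins <- function(mat, mad_factor = 1.5, min_mean_count = 10,
                             scaled_mad = FALSE) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  if (is.null(colnames(mat))) colnames(mat) <- seq_len(ncol(mat)) - 1
  const <- if (scaled_mad) 1.4826 else 1
  gene_id <- rownames(mat)
  status <- rep("binned", nrow(mat))
  peak_bin <- rep(NA_character_, nrow(mat))
  med <- mad_v <- peak_val <- rep(NA_real_, nrow(mat))

  low <- rowMeans(mat) < min_mean_count | rowSums(mat) == 0
  status[low] <- "excluded_low_count"

  keep <- which(!low)
  if (length(keep)) {
    pct <- mat[keep, , drop = FALSE] / rowSums(mat[keep, , drop = FALSE])
    med[keep] <- apply(pct, 1, median)
    mad_v[keep] <- apply(pct, 1, mad, constant = const)
    thr <- med[keep] + mad_factor * mad_v[keep]
    for (j in seq_along(keep)) {
      i <- keep[j]
      out <- which(pct[j, ] > thr[j])
      if (!length(out)) {
        status[i] <- "excluded_no_outlier"
      } else {
        top <- out[which.max(pct[j, out])]  # which.max: earliest on ties
        peak_bin[i] <- colnames(mat)[top]
        peak_val[i] <- pct[j, top]
      }
    }
  }
  data.frame(gene_id = gene_id, status = status, peak_bin = peak_bin,
             profile_median = med, profile_mad = mad_v,
             peak_value = peak_val, row.names = NULL)
}
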