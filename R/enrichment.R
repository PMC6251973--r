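## log(choose(n, k)) tail sums computed in log space to keep tiny
## p-values accurate.
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

hyper_tail <- function(x_range, N, K, m) {
  ## sum of P(X = x) over x_range for X ~ Hypergeometric(N, K, m)
  x_range <- x_range[x_range >= max(0, m - (N - K)) & x_range <= min(K, m)]
  if (!length(x_range)) return(0)
  lp <- lchoose(K, x_range) + lchoose(N - K, m - x_range) - lchoose(N, m)
  ## a full-support sum can land a few ulp above 1; probabilities are capped
  min(exp(log_sum_exp(lp)), 1)
}

#' Hypergeometric over/under-representation of a gene set in a bin
#'
#' With a universe of `N` genes of which `K` fall in the bin, and a query
#' set of `m` genes of which `x` overlap the bin, computes the one-sided
#' tail probabilities `p_over = P(X >= x)` and `p_under = P(X <= x)` for
#' `X ~ Hypergeometric(N, K, m)`. Tails are accumulated as log-space sums
#' of exact log point masses, so values far below double underflow of a
#' naive product remain accurate.
#'
#' @param set_members Character vector of query-set gene ids.
#' @param bin_members Character vector of bin gene ids.
#' @param universe Character vector of all gene ids under consideration;
#'   both other arguments must be subsets of it.
#' @return Data frame with one row: `universe_N`, `bin_K`, `set_m`,
#'   `overlap_x`, `p_over`, `p_under`.
#' @examples
#' hypergeometric_enrichment(letters[1:5], letters[1:5], letters[1:10])
#' @export
hypergeometric_enrichment <- function(set_members, bin_members, universe) {
  set_members <- unique(as.character(set_members))
  bin_members <- unique(as.character(bin_members))
  universe <- unique(as.character(universe))
  if (!all(set_members %in% universe))
    stop("not a subset: query set contains genes outside the universe")
  if (!all(bin_members %in% universe))
    stop("not a subset: bin contains genes outside the universe")
  N <- length(universe)
  K <- length(bin_members)
  m <- length(set_members)
  x <- length(intersect(set_members, bin_members))
  data.frame(universe_N = N, bin_K = K, set_m = m, overlap_x = x,
             p_over = hyper_tail(x:m, N, K, m),
             p_under = hyper_tail(0:x, N, K, m))
}

#' Enrichment of every peak bin for a gene set
#'
#' Convenience wrapper running [hypergeometric_enrichment()] of one gene
#' set against each peak bin of a [detect_peak_bins()] assignment table.
#' The universe is all binned genes unless given explicitly.
#'
#' @param set_members Character vector of query gene ids.
#' @param assignments Output of [detect_peak_bins()].
#' @param universe Universe gene ids; default: all genes with status
#'   `"binned"`.
#' @return Data frame with one row per bin plus the enrichment columns.
#' @export
bin_enrichment <- function(set_members, assignments, universe = NULL) {
  binned <- assignments[assignments$status == "binned", , drop = FALSE]
  if (is.null(universe)) universe <- binned$gene_id
  set_members <- intersect(unique(as.character(set_members)), universe)
  bins <- unique(binned$peak_bin)
  bins <- bins[order(suppressWarnings(as.numeric(bins)), bins)]
  res <- lapply(bins, function(b) {
    members <- intersect(binned$gene_id[binned$peak_bin == b], universe)
    cbind(bin = b, hypergeometric_enrichment(set_members, members, universe))
  })
  do.call(rbind, res)
}

#' Relative expression index of two signals
#'
#' `index = a / (a + b)`: 1 means only the first signal is expressed, 0
#' only the second, 0.5 equal expression. Vectorised over cells.
#'
#' @param signal_a,signal_b Non-negative signal intensities (e.g. per-cell
#'   FISH intensities of two genes).
#' @return Numeric vector of indices in \[0, 1\].
#' @export
expression_index <- function(signal_a, signal_b) {
  if (any(signal_a < 0) || any(signal_b < 0))
    stop("signals must be non-negative")
  tot <- signal_a + signal_b
  if (any(tot == 0)) stop("undefined index: both signals are zero")
  signal_a / tot
}

#' Overlap of a gene set with fold-change-affected genes
#'
#' Counts the query genes whose expression changed by at least
#' `fc_threshold`-fold in either direction (|log2 fold change| >=
#' log2(`fc_threshold`)) and tests the overlap against the universe genes
#' passing the same threshold with [hypergeometric_enrichment()].
#'
#' @param set_genes Character vector of query gene ids.
#' @param log2fc Named numeric vector of log2 fold changes; must cover
#'   every universe gene (and hence every query gene).
#' @param fc_threshold Fold-change cutoff on the natural scale.
#' @param universe Character vector of all tested gene ids.
#' @return One-row data frame as in [hypergeometric_enrichment()].
#' @export
fold_change_overlap <- function(set_genes, log2fc, fc_threshold = 1.5,
                                universe = names(log2fc)) {
  set_genes <- unique(as.character(set_genes))
  universe <- unique(as.character(universe))
  if (!all(universe %in% names(log2fc)))
    stop("every universe gene needs a fold-change value")
  affected <- universe[abs(log2fc[universe]) >= log2(fc_threshold)]
  hypergeometric_enrichment(set_genes, affected, universe)
}
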