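# Canonical study conditions used across tests: cell-cycle fixture with a
# ~7.4 h mean cycle, and the three fitted fate-parameter scenarios
# (wild-type glucose-rich, glucose-poor with a long checkpoint delay, and
# the reduced-plateau gefE-null-like setting).
canonical_cycle <- function() cycle_params(shape = 3, rate = 0.405, sigma = 1)

fate_gplus <- function() fate_params(chi = 1, lambda = 0.412, alpha = 0.4)
fate_gminus <- function() fate_params(chi = 1, lambda = 0.439, alpha = 2.1)
fate_gefe <- function() fate_params(chi = 0.813, lambda = 0.447, alpha = 1 / 3)

# Brute-force hypergeometric tails by enumerating every m-subset of the
# universe; independent of the log-space implementation.
fate_bin_labels_for_test <- function() c(as.character(0:10), "11+")

enum_hyper <- function(N, K, m, x) {
  if (m == 0)
    return(c(p_over = as.numeric(0 >= x), p_under = as.numeric(0 <= x)))
  draws <- utils::combn(N, m)
  in_bin <- colSums(matrix(draws <= K, nrow = m))
  c(p_over = mean(in_bin >= x), p_under = mean(in_bin <= x))
}
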