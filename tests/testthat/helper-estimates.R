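# Random full-rank state estimates for property-style tests.

random_psd_estimate <- function(k_s, k_a, seed, n = NULL) {
  set.seed(seed)
  study <- if (k_s > 0) paste0("s", seq_len(k_s)) else character()
  aux <- if (k_a > 0) paste0("a", seq_len(k_a)) else character()
  layout <- state_layout(study, times = 1, aux_names = aux)
  k <- layout$k
  if (is.null(n)) n <- k + 5L
  A <- matrix(rnorm(n * k), n, k)
  V <- crossprod(A) / n
  state_estimate(rnorm(k), V, layout = layout, n = n, validate = FALSE)
}

random_census <- function(layout, seed) {
  set.seed(seed)
  census_constants(stats::setNames(rnorm(layout$k_a), layout$aux), layout)
}

# A small sample table over a given layout, filled with iid normal values.
random_sample_table <- function(layout, n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * layout$k), n, layout$k)
  colnames(X) <- state_names(layout)
  data.frame(unit_id = seq_len(n), panel = layout$times[1L], X,
             check.names = FALSE)
}
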