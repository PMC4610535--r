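# Covariance hygiene: zero out off-diagonal covariances whose correlations
# are indistinguishable from chance.

#' Sparsification policy
#'
#' With hundreds of auxiliary variables, many estimated correlations with a
#' study variable are truly zero yet estimated as small nonzero values; each
#' one would shave a little variance off the constrained estimate, and the
#' shavings accumulate into a spurious reduction.  The policy tests every
#' off-diagonal correlation against zero and zeroes those compatible with
#' chance, before and/or after the Kalman run.
#'
#' @param alpha per-entry significance level of the two-sided test of zero
#'   correlation
#' @param n sample size that produced the covariance estimate
#' @param stage when to apply the policy in [run_pipeline()]
#' @param p_adjust multiplicity adjustment applied to the per-entry p-values
#'   before comparison with `alpha` (any method of [stats::p.adjust()];
#'   default `"none"`).  With many auxiliaries a per-entry level still
#'   admits `alpha` of the truly-null correlations, so a family-wise
#'   adjustment such as `"bonferroni"` is advisable when the auxiliary set
#'   is large.
#' @return an object of class `sparsify_policy`
#' @export
sparsify_policy <- function(alpha = 0.05, n,
                            stage = c("both", "before", "after"),
                            p_adjust = "none") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n < 4) stop("n must be at least 4")
  structure(list(alpha = alpha, n = as.integer(n), stage = match.arg(stage),
                 p_adjust = p_adjust),
            class = "sparsify_policy")
}

#' Zero covariances whose correlations are compatible with chance
#'
#' For every off-diagonal entry the implied correlation `r` is tested
#' against zero with the t statistic `r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom; entries that are not significant at
#' `policy$alpha` are set exactly to zero.  The diagonal is untouched.  A
#' correlation of exactly +/-1 makes the statistic degenerate and the entry
#' is kept.  Entries involving a zero-variance variable carry no
#' information and are zeroed.  If the zeroing destroys positive
#' semidefiniteness the matrix is repaired by clipping negative eigenvalues
#' at zero (this can perturb the diagonal; the repair is flagged).
#'
#' @param est a [state_estimate()]
#' @param policy a [sparsify_policy()]; its `n` must be the sample size
#'   behind `est`
#' @return list with `estimate` (sparsified), `zeroed` (two-column matrix of
#'   zeroed index pairs, i < j) and `repaired` (logical)
#' @export
sparsify <- function(est, policy) {
  stopifnot(inherits(est, "state_estimate"), inherits(policy, "sparsify_policy"))
  V <- est$V
  k <- nrow(V)
  n <- policy$n
  d <- diag(V)
  if (k < 2L) {
    return(list(estimate = est, zeroed = matrix(integer(), 0, 2),
                repaired = FALSE))
  }

  pairs <- which(upper.tri(V), arr.ind = TRUE)
  vij <- V[pairs]
  di <- d[pairs[, 1L]]
  dj <- d[pairs[, 2L]]
  r <- ifelse(di > 0 & dj > 0, vij / sqrt(di * dj), 0)
  r <- pmin(pmax(r, -1), 1)
  degenerate <- abs(r) >= 1 & vij != 0
  tstat <- ifelse(abs(r) < 1, r * sqrt((n - 2) / (1 - r^2)), Inf)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- stats::p.adjust(p, method = policy$p_adjust)
  drop <- (p >= policy$alpha) & !degenerate

  zeroed <- pairs[drop, , drop = FALSE]
  if (nrow(zeroed)) {
    V[zeroed] <- 0
    V[zeroed[, c(2L, 1L), drop = FALSE]] <- 0
  }

  repaired <- FALSE
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(d, 1e-300)) {
    V <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    V <- (V + t(V)) / 2
    repaired <- TRUE
  }
  dimnames(V) <- dimnames(est$V)
  out <- state_estimate(est$x, V, layout = est$layout, pseudo = est$pseudo,
                        n = est$n, validate = FALSE)
  list(estimate = out, zeroed = unname(zeroed), repaired = repaired)
}
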