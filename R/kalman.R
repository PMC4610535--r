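# Sequential scalar Kalman measurement update with exact census constraints,
# plus the batch closed form used as an independent cross-check.

#' Options for the sequential Kalman update
#'
#' @param tol variance threshold: an auxiliary whose current diagonal
#'   variance is below `tol` is skipped (its scalar inverse would be
#'   numerically explosive, and a near-zero variance means the constraint is
#'   already essentially satisfied).  The threshold applies on the scale the
#'   update is run on; the recommended pipeline standardizes first, making
#'   `tol = 1e-4` one ten-thousandth of a unit variance.
#' @param divergence divergence handling for implausibly large residuals
#'   between a sample estimate and its census constant:
#'   `"as_printed"` computes `c = 2 |y - x_k| / V_kk` and, when `c > 1`,
#'   inflates row and column `k` of `V` by `c` (the diagonal by `c^2`);
#'   `"two_sigma"` triggers when the residual exceeds two standard
#'   deviations and inflates so the post-inflation residual is exactly two
#'   standard deviations; `"off"` never inflates.  The two rules differ: the
#'   first compares the residual to a variance, the second to a standard
#'   deviation.  Both are provided; see the package vignette.
#' @param order processing order over the auxiliary block; the default works
#'   from the last auxiliary down to the first.  With divergence off the
#'   final estimate is order-invariant.
#' @return an object of class `kf_options`
#' @export
kf_options <- function(tol = 1e-4,
                       divergence = c("as_printed", "two_sigma", "off"),
                       order = c("descending", "ascending")) {
  if (tol < 0) stop("tol must be nonnegative")
  structure(list(tol = tol, divergence = match.arg(divergence),
                 order = match.arg(order)),
            class = "kf_options")
}

#' Sequential Kalman update with exact census constraints
#'
#' Updates a design-based state estimate so that every auxiliary mean equals
#' its exact census value, processing one auxiliary at a time.  Each scalar
#' step needs only the inverse of one diagonal variance, so the update is
#' robust to an ill-conditioned or rank-deficient auxiliary covariance block:
#' redundant auxiliaries are skipped once an earlier constraint has driven
#' their variance below `tol`.  After a constraint is applied, the estimate
#' of that auxiliary equals its census constant exactly and its covariance
#' row and column are exactly zero -- the step orthogonalises the constrained
#' variable against the rest of the state.
#'
#' With divergence handling off, every study-variable variance is
#' non-increasing: conditioning on an exact constant can only remove
#' variance.  A study variable with zero covariance to every auxiliary is
#' left untouched.
#'
#' @param est a [state_estimate()] aligned to a layout with `k_a >= 1`
#'   (with `k_a = 0` the update is the identity)
#' @param census a `census_constants` object (or bare numeric vector of
#'   length `k_a`, aligned to the auxiliary block)
#' @param options a [kf_options()]
#' @return an object of class `kf_result`: list with `estimate` (the updated
#'   [state_estimate()]) and `audit`, a data frame with one row per
#'   auxiliary recording `status` (`applied`, `skipped_low_variance` or
#'   `inflated_then_applied`), the inflation factor `c` when any, the
#'   residual in standard-deviation units, and the weight-vector norm
#' @examples
#' lay <- state_layout("y", 1, "a")
#' est <- state_estimate(c(1, 2), matrix(c(1, .5, .5, 1), 2), lay)
#' res <- kf_sequential(est, census_constants(c(a = 3), lay))
#' res$estimate$x   # y pulled to 1.5, a constrained to 3
#' @seealso [kf_batch()] for the closed-form equivalent on full-rank input
#' @export
kf_sequential <- function(est, census, options = kf_options()) {
  stopifnot(inherits(est, "state_estimate"), inherits(options, "kf_options"))
  layout <- est$layout
  if (is.null(layout)) stop("estimate carries no layout")
  if (length(est$pseudo)) {
    stop("post-estimation pseudo variables must not be fed back into the ",
         "Kalman update")
  }
  y <- if (inherits(census, "census_constants")) census$y else as.numeric(census)
  if (length(y) != layout$k_a) {
    stop("census has length ", length(y), " but layout expects ", layout$k_a)
  }
  if (any(!is.finite(est$x)) || any(!is.finite(est$V)) || any(!is.finite(y))) {
    stop("non-finite inputs to the Kalman update")
  }

  x <- est$x
  V <- est$V
  ks <- layout$k_s
  ka <- layout$k_a
  audit <- data.frame(
    index = integer(ka), state_index = integer(ka),
    name = character(ka), status = character(ka),
    c = rep(NA_real_, ka), residual_sd = rep(NA_real_, ka),
    weight_norm = rep(NA_real_, ka), stringsAsFactors = FALSE
  )
  steps <- if (ka == 0L) integer() else switch(options$order,
    descending = ka:1L, ascending = 1L:ka)

  row <- 0L
  for (i in steps) {
    row <- row + 1L
    kk <- ks + i
    audit$index[row] <- i
    audit$state_index[row] <- kk
    audit$name[row] <- layout$aux[i]
    vkk <- V[kk, kk]
    if (vkk < options$tol) {
      audit$status[row] <- "skipped_low_variance"
      next
    }
    resid <- unname(y[i] - x[kk])
    audit$residual_sd[row] <- abs(resid) / sqrt(vkk)
    cfac <- NA_real_
    if (options$divergence == "as_printed") {
      cc <- 2 * abs(resid) / vkk
      if (cc > 1) {
        V[, kk] <- V[, kk] * cc
        V[kk, ] <- V[kk, ] * cc
        cfac <- cc
      }
    } else if (options$divergence == "two_sigma") {
      if (abs(resid) > 2 * sqrt(vkk)) {
        cc <- abs(resid) / (2 * sqrt(vkk))
        V[, kk] <- V[, kk] * cc
        V[kk, ] <- V[kk, ] * cc
        cfac <- cc
      }
    }
    vkk <- V[kk, kk]
    vk <- V[, kk]
    w <- vk / vkk
    x <- x + w * (y[i] - x[kk])
    V <- V - tcrossprod(vk) / vkk
    # enforce the exact constraint: no float dust on the orthogonalised
    # coordinate
    x[kk] <- y[i]
    V[kk, ] <- 0
    V[, kk] <- 0
    if (any(!is.finite(x)) || any(!is.finite(V))) {
      stop("non-finite values produced while applying auxiliary ", i,
           " ('", layout$aux[i], "')")
    }
    audit$status[row] <- if (is.na(cfac)) "applied" else "inflated_then_applied"
    audit$c[row] <- cfac
    audit$weight_norm[row] <- sqrt(sum(w^2))
  }
  V <- (V + t(V)) / 2
  out <- state_estimate(x, V, layout = layout, n = est$n, validate = FALSE)
  structure(list(estimate = out, audit = audit), class = "kf_result")
}

#' @export
print.kf_result <- function(x, ...) {
  tab <- table(factor(x$audit$status,
                      levels = c("applied", "inflated_then_applied",
                                 "skipped_low_variance")))
  cat("Kalman update:", tab[["applied"]], "constraint(s) applied,",
      tab[["inflated_then_applied"]], "inflated then applied,",
      tab[["skipped_low_variance"]], "skipped (low variance)\n")
  invisible(x)
}

#' One scalar Kalman step for a single auxiliary constraint
#'
#' Applies the constraint `x[k] = y_i` for the `aux_index`-th auxiliary by
#' the rank-one conditioning update with weight vector `w = V[, k] / V[k, k]`.
#' The constrained coordinate's weight is always 1, so its estimate equals
#' `y_i` exactly; its covariance row and column are zeroed.
#'
#' @param est a [state_estimate()]
#' @param aux_index position within the auxiliary block (1..k_a)
#' @param y_i the census constant
#' @param tol minimum variance at the constrained coordinate
#' @return the updated [state_estimate()]
#' @export
scalar_step <- function(est, aux_index, y_i, tol = 1e-12) {
  stopifnot(inherits(est, "state_estimate"))
  layout <- est$layout
  kk <- layout$k_s + aux_index
  if (est$V[kk, kk] < tol) {
    stop("variance at auxiliary ", aux_index, " is below tol")
  }
  x <- est$x
  V <- est$V
  vk <- V[, kk]
  w <- vk / V[kk, kk]
  x <- x + w * (y_i - x[kk])
  V <- V - tcrossprod(vk) / V[kk, kk]
  x[kk] <- y_i
  V[kk, ] <- 0
  V[, kk] <- 0
  state_estimate(x, (V + t(V)) / 2, layout = layout, n = est$n,
                 validate = FALSE)
}

#' Covariance inflation against filter divergence
#'
#' A suspiciously large residual between the sample estimate of an auxiliary
#' mean and its census constant signals non-sampling error (or an extreme
#' sampling error): applied at face value it would receive too much weight
#' and "diverge" the filter.  The mitigation inflates the auxiliary's
#' covariance row and column so it is down-weighted.
#'
#' @inheritParams scalar_step
#' @param mode `"as_printed"`, `"two_sigma"` or `"off"`; see [kf_options()]
#' @return list with `estimate` (possibly inflated) and `c` (the factor
#'   applied to the row and column, or `NA` when no inflation occurred)
#' @export
divergence_inflate <- function(est, aux_index, y_i,
                               mode = c("as_printed", "two_sigma", "off")) {
  mode <- match.arg(mode)
  stopifnot(inherits(est, "state_estimate"))
  kk <- est$layout$k_s + aux_index
  V <- est$V
  vkk <- V[kk, kk]
  resid <- unname(y_i - est$x[kk])
  cfac <- NA_real_
  if (mode == "as_printed") {
    cc <- 2 * abs(resid) / vkk
    if (cc > 1) cfac <- cc
  } else if (mode == "two_sigma") {
    if (abs(resid) > 2 * sqrt(vkk)) cfac <- abs(resid) / (2 * sqrt(vkk))
  }
  if (!is.na(cfac)) {
    V[, kk] <- V[, kk] * cfac
    V[kk, ] <- V[kk, ] * cfac
  }
  list(estimate = state_estimate(est$x, V, layout = est$layout,
                                 n = est$n, validate = FALSE),
       c = cfac)
}

#' Batch closed-form constrained estimate
#'
#' The one-shot matrix form of the constrained estimator:
#' `W = V H' (H V H')^{-1}`, `x' = (I - W H) x + W y`,
#' `V' = (I - W H) V (I - W H)'`.  It requires the auxiliary covariance
#' block to be invertible (or a pseudo-inverse to be allowed) and is used as
#' the independent cross-check for [kf_sequential()].
#'
#' @param est a [state_estimate()]
#' @param census a `census_constants` or numeric vector of length `k_a`
#' @param pseudo_inverse use the Moore-Penrose pseudo-inverse when the
#'   auxiliary block is singular
#' @return the constrained [state_estimate()]
#' @export
kf_batch <- function(est, census, pseudo_inverse = FALSE) {
  stopifnot(inherits(est, "state_estimate"))
  layout <- est$layout
  if (is.null(layout)) stop("estimate carries no layout")
  y <- if (inherits(census, "census_constants")) census$y else as.numeric(census)
  if (layout$k_a == 0L) return(est)
  aidx <- selection_indices(layout)
  A <- est$V[aidx, aidx, drop = FALSE]
  Ainv <- if (pseudo_inverse) {
    MASS::ginv(A)
  } else {
    rc <- rcond(A)
    if (!is.finite(rc) || rc < 1e-12) {
      stop("auxiliary covariance block is singular; set pseudo_inverse = TRUE")
    }
    solve(A)
  }
  W <- est$V[, aidx, drop = FALSE] %*% Ainv
  x <- est$x + as.vector(W %*% (y - est$x[aidx]))
  IWH <- diag(length(est$x))
  IWH[, aidx] <- IWH[, aidx] - W
  V <- IWH %*% est$V %*% t(IWH)
  state_estimate(x, (V + t(V)) / 2, layout = layout, n = est$n,
                 validate = FALSE)
}

# Transform census constants onto the scale of a standardized estimate.
standardize_census <- function(census, transform, layout) {
  y <- if (inherits(census, "census_constants")) census$y else as.numeric(census)
  aidx <- selection_indices(layout)
  (y - transform$center[aidx]) / transform$scale[aidx]
}

#' Standardize, update, destandardize
#'
#' The recommended invocation: centre and scale state space to unit diagonal
#' (so `tol` is scale-free and the arithmetic is well conditioned), run the
#' sequential update with the census constants mapped onto the same scale,
#' and transform back.
#'
#' @inheritParams kf_sequential
#' @return a `kf_result` on the original scale
#' @export
kf_estimate <- function(est, census, options = kf_options()) {
  std <- standardize(est)
  ys <- standardize_census(census, std$transform, est$layout)
  res <- kf_sequential(std$estimate, ys, options)
  res$estimate <- destandardize(res$estimate, std$transform)
  res
}
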