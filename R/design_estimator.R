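# Design-based initial estimator, census constants, eligibility filtering,
# panel pooling and the post-stratification comparator.

# Align a sample table's value columns to the layout's state-name order and
# return the n-by-k numeric matrix.
sample_values <- function(sample, layout, require_complete = TRUE) {
  nm <- state_names(layout)
  reserved <- c("unit_id", "panel", "stratum")
  have <- setdiff(colnames(sample), reserved)
  missing <- setdiff(nm, have)
  if (length(missing)) {
    stop("sample is missing state-variable column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(have, nm)
  if (length(extra)) {
    stop("sample has unknown column(s): ", paste(extra, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(sample)[, nm, drop = FALSE])
  if (!is.numeric(X)) stop("non-numeric values in sample table")
  if (require_complete && any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop("non-finite value in sample at row ", bad[1L],
         ", column '", nm[bad[2L]], "'")
  }
  X
}

#' Design-based simple random sampling estimate of the state vector
#'
#' Computes the vector sample mean and the covariance matrix of the mean,
#' `V = S / n` with `S` the sample covariance (divisor `n - 1`).  This is the
#' multivariate design-based estimator for a simple random sample in which
#' every sampled unit carries the full measurement vector; it initialises the
#' Kalman update.  No finite-population correction is applied.
#'
#' @param sample a sample table: data frame with columns `unit_id`, `panel`,
#'   optionally `stratum`, and one numeric column per state variable named as
#'   in [state_names()]
#' @param layout the [state_layout()] the columns align to
#' @return a [state_estimate()] with the sample size recorded in `$n`
#' @examples
#' lay <- state_layout("y", 1, "a")
#' s <- data.frame(unit_id = 1:3, panel = 1, y.1 = c(0, 2, 4), a = c(2, 4, 6))
#' est <- srs_estimate(s, lay)
#' est$x
#' @export
srs_estimate <- function(sample, layout) {
  X <- sample_values(sample, layout)
  n <- nrow(X)
  if (n < 2L) stop("at least 2 sampled units are required (got ", n, ")")
  x <- colMeans(X)
  V <- stats::cov(X) / n
  V <- (V + t(V)) / 2
  state_estimate(x, V, layout = layout, n = n, validate = FALSE)
}

#' Census constants for the auxiliary variables
#'
#' Enumerates the exact population mean of every auxiliary variable over all
#' `N` population units.  These means carry no sampling error: they are the
#' known observation vector the Kalman update constrains the state to.
#'
#' @param population either a [generate_population()] result or a data frame /
#'   matrix of `N` rows with (at least) the auxiliary columns named per the
#'   layout
#' @param layout the [state_layout()]
#' @return object of class `census_constants`: list with `y` (named
#'   `k_a`-vector) and `N`
#' @export
enumerate_census <- function(population, layout) {
  stopifnot(inherits(layout, "state_layout"))
  if (inherits(population, "finite_population")) {
    values <- population$values
  } else {
    values <- as.data.frame(population)
  }
  if (nrow(values) < 1L) stop("empty population")
  missing <- setdiff(layout$aux, colnames(values))
  if (length(missing)) {
    stop("population is missing auxiliary column(s): ",
         paste(missing, collapse = ", "))
  }
  A <- as.matrix(values[, layout$aux, drop = FALSE])
  if (any(!is.finite(A))) stop("non-finite auxiliary values in population")
  census_constants(colMeans(A), layout, N = nrow(values))
}

#' @rdname enumerate_census
#' @param y named numeric vector of exact auxiliary means
#' @param N population size (metadata)
#' @export
census_constants <- function(y, layout, N = NA_integer_) {
  stopifnot(inherits(layout, "state_layout"))
  y <- unlist(y)
  if (length(y) != layout$k_a) {
    stop("expected ", layout$k_a, " census constants, got ", length(y))
  }
  if (!is.null(names(y)) && layout$k_a > 0L) {
    missing <- setdiff(layout$aux, names(y))
    if (length(missing)) {
      stop("census is missing auxiliary variable(s): ",
           paste(missing, collapse = ", "))
    }
    extra <- setdiff(names(y), layout$aux)
    if (length(extra)) {
      stop("census has unknown variable(s): ", paste(extra, collapse = ", "))
    }
    y <- y[layout$aux]
  } else {
    names(y) <- layout$aux
  }
  if (any(!is.finite(y))) stop("non-finite census constants")
  y <- stats::setNames(as.numeric(y), layout$aux)
  structure(list(y = y, N = N), class = "census_constants")
}

#' @export
print.census_constants <- function(x, ...) {
  cat("Census constants for", length(x$y), "auxiliary variable(s)",
      if (!is.na(x$N)) paste0("(N = ", x$N, ")"), "\n")
  print(x$y)
  invisible(x)
}

#' Eligibility filter: require enough nonzero measurements
#'
#' Estimated covariances for rare variables are unreliable: a variable with
#' few nonzero measured values can by chance appear highly correlated with a
#' study variable and spuriously shrink its variance.  Only variables with a
#' nonzero measured value on at least `min_nonzero` sampled units are kept.
#' A study variable is assessed at every time step and dropped entirely if it
#' fails at any one of them; auxiliary variables are assessed individually.
#'
#' @param sample sample table (see [srs_estimate()])
#' @param layout the [state_layout()]
#' @param min_nonzero minimum number of sampling units with a nonzero value
#' @return list with `kept` and `dropped` state-vector indices and a
#'   `layout` reduced to the kept variables
#' @export
eligibility_filter <- function(sample, layout, min_nonzero = 25) {
  X <- sample_values(sample, layout, require_complete = FALSE)
  nz <- colSums(X != 0, na.rm = TRUE)
  nm <- state_names(layout)
  keep_col <- nz >= min_nonzero

  keep_study <- layout$study
  if (length(layout$study)) {
    ok <- vapply(layout$study, function(v) {
      idx <- vapply(layout$times,
                    function(t) state_index(layout, v, t), integer(1))
      all(keep_col[idx])
    }, logical(1))
    keep_study <- layout$study[ok]
  }
  keep_aux <- layout$aux[keep_col[layout$k_s + seq_len(layout$k_a)]]

  reduced <- state_layout(keep_study, layout$times, keep_aux)
  kept <- match(state_names(reduced), nm)
  list(kept = sort(kept),
       dropped = setdiff(seq_len(layout$k), kept),
       layout = reduced)
}

#' Pool annual panels over a moving window
#'
#' In a rotating panel design only a fraction of the units is measured each
#' year; pooling a window of consecutive panels augments the sample size for
#' small areas, at the cost of temporal smoothing.  The default window ends
#' at the anchor time (a report "for" a year uses that year and the two
#' prior); `align = "centered"` centres it instead.  Windows are truncated at
#' the edges of the series.
#'
#' @param sample sample table with a `panel` column
#' @param layout the [state_layout()] (supplies the time ordering)
#' @param anchor_time the time the pooled estimate is reported for
#' @param window number of consecutive panels pooled (>= 1)
#' @param align `"trailing"` (default) or `"centered"`
#' @return the sub-table of rows whose panel falls in the window; duplicate
#'   `unit_id`s across panels are kept as distinct rows
#' @export
pool_panels <- function(sample, layout, anchor_time, window = 3,
                        align = c("trailing", "centered")) {
  align <- match.arg(align)
  if (window < 1L) stop("window must be >= 1")
  times <- as.character(layout$times)
  pos <- match(as.character(anchor_time), times)
  if (is.na(pos)) stop("unknown anchor time: ", anchor_time)
  if (align == "trailing") {
    lo <- max(1L, pos - window + 1L)
    hi <- pos
  } else {
    half <- (window - 1L) %/% 2L
    lo <- max(1L, pos - half)
    hi <- min(length(times), pos + (window - 1L) - half)
  }
  keep <- as.character(sample$panel) %in% times[lo:hi]
  sample[keep, , drop = FALSE]
}

#' Post-stratified estimate with small-stratum collapsing
#'
#' The conventional comparator to the Kalman update: the sample is
#' partitioned after selection by a categorical auxiliary classification and
#' stratum means are reweighted by known population stratum weights.  Strata
#' with fewer than `min_per_stratum` sampled units are merged into a
#' designated "similar" stratum (in the order given by `collapse_map`)
#' before estimation.  If merging cannot bring every stratum up to size, the
#' estimator falls back to simple random sampling and flags it.
#'
#' The variance estimator is
#' \deqn{\hat V = \frac{1}{n}\sum_h W_h s_h^2 +
#'       \frac{1}{n^2}\sum_h (1 - W_h) s_h^2,}
#' the standard form whose second term adjusts for the random sample size
#' realised within each stratum.
#'
#' @param sample sample table with a `stratum` column
#' @param layout the [state_layout()]
#' @param stratum_weights named numeric vector of known population stratum
#'   weights (proportions of the population; must sum to 1)
#' @param min_per_stratum minimum sampled units per stratum before collapsing
#' @param collapse_map named character vector: `collapse_map["A"] == "B"`
#'   means a too-small stratum A merges into B; applied in order, repeatedly,
#'   until all strata reach size or no merge applies
#' @return data frame with one row per state variable: `variable`, `mean`,
#'   `variance`; attributes `fallback` (logical), `merges` (character log)
#'   and `strata` (final stratum sizes)
#' @export
poststratified_estimate <- function(sample, layout, stratum_weights,
                                    min_per_stratum = 10,
                                    collapse_map = NULL) {
  if (is.null(sample$stratum)) stop("sample has no 'stratum' column")
  if (abs(sum(stratum_weights) - 1) > 1e-8) {
    stop("stratum weights must sum to 1")
  }
  X <- sample_values(sample, layout)
  n <- nrow(X)
  strat <- as.character(sample$stratum)
  unknown <- setdiff(strat, names(stratum_weights))
  if (length(unknown)) {
    stop("sampled stratum without a weight: ", paste(unique(unknown), collapse = ", "))
  }
  w <- stratum_weights

  merges <- character()
  repeat {
    counts <- table(factor(strat, levels = names(w)))
    small <- names(counts)[counts < min_per_stratum]
    if (!length(small)) break
    cand <- intersect(names(collapse_map), small)
    cand <- cand[collapse_map[cand] %in% names(w)]
    if (!length(cand)) break
    from <- cand[1L]
    to <- collapse_map[[from]]
    strat[strat == from] <- to
    w[to] <- w[to] + w[from]
    w <- w[names(w) != from]
    merges <- c(merges, paste(from, "->", to))
  }
  counts <- table(factor(strat, levels = names(w)))

  nm <- state_names(layout)
  if (any(counts < min_per_stratum)) {
    est <- srs_estimate(sample, layout)
    out <- data.frame(variable = nm, mean = unname(est$x),
                      variance = unname(diag(est$V)))
    attr(out, "fallback") <- TRUE
    attr(out, "merges") <- merges
    attr(out, "strata") <- counts
    return(out)
  }

  strata <- names(w)
  mu <- matrix(0, length(strata), ncol(X), dimnames = list(strata, nm))
  s2 <- mu
  for (h in strata) {
    Xh <- X[strat == h, , drop = FALSE]
    mu[h, ] <- colMeans(Xh)
    s2[h, ] <- apply(Xh, 2, stats::var)
  }
  W <- w[strata]
  mean_est <- as.vector(W %*% mu)
  var_est <- as.vector(W %*% s2) / n + as.vector((1 - W) %*% s2) / n^2

  out <- data.frame(variable = nm, mean = mean_est, variance = var_est)
  attr(out, "fallback") <- FALSE
  attr(out, "merges") <- merges
  attr(out, "strata") <- counts
  out
}

#' Design effect relative to simple random sampling
#'
#' `100 * (1 - v_est / v_srs)`: the percent reduction in estimated variance
#' relative to the simple random sampling estimator.  Positive values are
#' efficiency gains; negative values mean the estimator is less efficient
#' than SRS.
#'
#' @param v_est variance of the estimator under evaluation
#' @param v_srs variance of the SRS estimator (must be positive)
#' @return design effect in percent (vectorised)
#' @examples
#' design_effect(0.9, 1.0)   # 10
#' design_effect(1.2, 1.0)   # -20
#' @export
design_effect <- function(v_est, v_srs) {
  if (any(v_srs <= 0)) stop("v_srs must be positive")
  100 * (1 - v_est / v_srs)
}
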