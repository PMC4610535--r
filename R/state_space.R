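#' Build a state-vector layout
#'
#' The state vector stacks population means for every study variable at every
#' time step, followed by the auxiliary variables.  The study block is
#' organised time-by-time: all study variables at the first time, then all
#' study variables at the second time, and so on; the auxiliary block follows.
#' The layout records this bookkeeping so that estimates, covariance matrices
#' and census constants can be aligned by name rather than by position.
#'
#' @param study_names character vector of study-variable identifiers
#'   (unique).  May be empty.
#' @param times vector of time labels (unique, in temporal order).  Study
#'   variables are replicated once per time.
#' @param aux_names character vector of auxiliary-variable identifiers
#'   (unique).  May be empty.
#' @return An object of class `state_layout` with elements `study`, `times`,
#'   `aux`, and the counts `k_s` (= number of study variables times number of
#'   times), `k_a` and `k = k_s + k_a`.
#' @examples
#' lay <- state_layout(c("ba", "mortality"), times = 2002:2004, "forest_cover")
#' lay$k        # 7
#' state_names(lay)
#' @seealso [state_names()], [state_index()], [selection_indices()]
#' @export
state_layout <- function(study_names, times, aux_names = character()) {
  study_names <- as.character(study_names)
  aux_names <- as.character(aux_names)
  if (anyDuplicated(study_names)) {
    stop("duplicate study names: ",
         paste(unique(study_names[duplicated(study_names)]), collapse = ", "))
  }
  if (anyDuplicated(aux_names)) {
    stop("duplicate auxiliary names: ",
         paste(unique(aux_names[duplicated(aux_names)]), collapse = ", "))
  }
  if (anyDuplicated(times)) {
    stop("duplicate time labels: ",
         paste(unique(times[duplicated(times)]), collapse = ", "))
  }
  if (length(study_names) > 0L && length(times) == 0L) {
    stop("at least one time label is required when study variables exist")
  }
  if (is.numeric(times) && is.unsorted(times, strictly = TRUE)) {
    stop("numeric time labels must be strictly increasing")
  }
  k_s <- length(study_names) * length(times)
  k_a <- length(aux_names)
  structure(
    list(study = study_names, times = times, aux = aux_names,
         k_s = k_s, k_a = k_a, k = k_s + k_a),
    class = "state_layout"
  )
}

#' @export
print.state_layout <- function(x, ...) {
  cat("State layout:", length(x$study), "study variable(s) x",
      length(x$times), "time(s) (k_s =", x$k_s, "), ",
      x$k_a, "auxiliary variable(s); k =", x$k, "\n")
  invisible(x)
}

#' State-variable names in layout order
#'
#' Study variables are named `<name>.<time>`; auxiliary names are used as-is.
#'
#' @param layout a [state_layout()]
#' @return character vector of length `layout$k`
#' @export
state_names <- function(layout) {
  stopifnot(inherits(layout, "state_layout"))
  if (layout$k_s > 0L) {
    study <- as.vector(vapply(
      as.character(layout$times),
      function(t) paste(layout$study, t, sep = "."),
      character(length(layout$study))
    ))
  } else {
    study <- character()
  }
  c(study, layout$aux)
}

#' Position of a state variable in the state vector
#'
#' @param layout a [state_layout()]
#' @param name variable identifier (study or auxiliary)
#' @param time time label, required for study variables, ignored for
#'   auxiliary variables
#' @return integer index into the state vector (1-based)
#' @export
state_index <- function(layout, name, time = NULL) {
  stopifnot(inherits(layout, "state_layout"))
  if (name %in% layout$aux) {
    return(layout$k_s + match(name, layout$aux))
  }
  j <- match(name, layout$study)
  if (is.na(j)) stop("unknown state variable: ", name)
  if (is.null(time)) stop("a time label is required for study variable ", name)
  t_pos <- match(as.character(time), as.character(layout$times))
  if (is.na(t_pos)) stop("unknown time label: ", time)
  (t_pos - 1L) * length(layout$study) + j
}

#' Invert a state-vector index to its (variable, time) identity
#'
#' @param layout a [state_layout()]
#' @param i index (1-based)
#' @return a list with `name`, `time` (`NA` for auxiliaries) and `block`
#'   (`"study"` or `"aux"`)
#' @export
state_identity <- function(layout, i) {
  stopifnot(inherits(layout, "state_layout"), i >= 1L, i <= layout$k)
  if (i > layout$k_s) {
    list(name = layout$aux[i - layout$k_s], time = NA, block = "aux")
  } else {
    n_study <- length(layout$study)
    t_pos <- (i - 1L) %/% n_study + 1L
    j <- (i - 1L) %% n_study + 1L
    list(name = layout$study[j], time = layout$times[t_pos], block = "study")
  }
}

#' Indices of the auxiliary block
#'
#' The measurement matrix H = \[0 | I\] of the Kalman update selects the
#' trailing auxiliary partition of the state vector.  It is represented as an
#' index range; [selection_matrix()] materialises the dense binary matrix for
#' checking purposes.
#'
#' @param layout a [state_layout()]
#' @return integer vector of length `layout$k_a` (empty when there is no
#'   auxiliary block)
#' @export
selection_indices <- function(layout) {
  stopifnot(inherits(layout, "state_layout"))
  if (layout$k_a == 0L) return(integer())
  (layout$k_s + 1L):layout$k
}

#' Dense measurement matrix H = \[0 | I\]
#'
#' @param layout a [state_layout()]
#' @return a `k_a` by `k` binary matrix
#' @export
selection_matrix <- function(layout) {
  idx <- selection_indices(layout)
  H <- matrix(0, length(idx), layout$k)
  if (length(idx)) H[cbind(seq_along(idx), idx)] <- 1
  H
}

#' Construct a state estimate (vector mean plus covariance)
#'
#' A state estimate couples the estimated state vector `x` with the covariance
#' matrix `V` of its estimation errors.  `V` must be symmetric and positive
#' semidefinite within tolerance; small asymmetries from floating-point
#' arithmetic are symmetrised away.
#'
#' @param x numeric vector of length `k`
#' @param V `k` by `k` covariance matrix
#' @param layout the [state_layout()] the estimate is aligned to (optional
#'   but required by the Kalman update)
#' @param pseudo names of appended post-estimation variables, if any; the
#'   estimate then has length `layout$k + length(pseudo)`
#' @param n sample size that produced the estimate (metadata, used by
#'   [sparsify()])
#' @param validate check symmetry and positive semidefiniteness
#' @return an object of class `state_estimate`
#' @export
state_estimate <- function(x, V, layout = NULL, pseudo = character(),
                           n = NA_integer_, validate = TRUE) {
  x <- as.numeric(x)
  V <- as.matrix(V)
  k <- length(x)
  if (!all(dim(V) == k)) {
    stop("V must be ", k, " by ", k, ", got ", nrow(V), " by ", ncol(V))
  }
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "state_layout"))
    if (k != layout$k + length(pseudo)) {
      stop("estimate has length ", k, " but layout expects ",
           layout$k + length(pseudo))
    }
    nm <- c(state_names(layout), pseudo)
  } else {
    nm <- if (!is.null(names(x))) names(x) else c(rownames(V), NULL)
  }
  if (validate) {
    if (any(!is.finite(x)) || any(!is.finite(V))) {
      stop("non-finite entries in state estimate")
    }
    scale <- max(abs(V), 1e-300)
    asym <- max(abs(V - t(V))) / scale
    if (asym > 1e-10) {
      stop("V is not symmetric (relative asymmetry ", format(asym), ")")
    }
    V <- (V + t(V)) / 2
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(diag(V), 1e-300)) {
      stop("V is not positive semidefinite (min eigenvalue ",
           format(min(ev)), ")")
    }
  }
  if (!is.null(nm) && length(nm) == k) {
    names(x) <- nm
    dimnames(V) <- list(nm, nm)
  }
  structure(list(x = x, V = V, layout = layout, pseudo = pseudo, n = n),
            class = "state_estimate")
}

#' @export
print.state_estimate <- function(x, ...) {
  k <- length(x$x)
  cat("State estimate with", k, "element(s)")
  if (!is.null(x$layout)) {
    cat(" (k_s =", x$layout$k_s, ", k_a =", x$layout$k_a)
    if (length(x$pseudo)) cat(",", length(x$pseudo), "pseudo")
    cat(")")
  }
  cat("\n")
  show <- data.frame(estimate = x$x, SE = sqrt(pmax(diag(x$V), 0)))
  print(utils::head(show, 10L))
  if (k > 10L) cat("... and", k - 10L, "more\n")
  invisible(x)
}

#' Centre and scale a state estimate to unit diagonal
#'
#' Numerical conditioning of the Kalman update improves when state space is
#' centred on the zero vector and scaled so the covariance matrix has a unit
#' diagonal.  Variables with zero variance keep scale 1 (they are skipped by
#' the update's variance threshold downstream).  [destandardize()] inverts
#' the transform exactly.
#'
#' @param est a [state_estimate()]
#' @return list with `estimate` (the standardized [state_estimate()]) and
#'   `transform` (class `standardization`, with `center` and `scale`)
#' @export
standardize <- function(est) {
  stopifnot(inherits(est, "state_estimate"))
  if (any(!is.finite(est$x)) || any(!is.finite(est$V))) {
    stop("non-finite entries in state estimate")
  }
  center <- est$x
  d <- diag(est$V)
  scale <- ifelse(d > 0, sqrt(d), 1)
  Vs <- est$V / outer(scale, scale)
  xs <- (est$x - center) / scale
  out <- state_estimate(xs, Vs, layout = est$layout, pseudo = est$pseudo,
                        n = est$n, validate = FALSE)
  transform <- structure(list(center = center, scale = scale),
                         class = "standardization")
  list(estimate = out, transform = transform)
}

#' @rdname standardize
#' @param transform a `standardization` returned by [standardize()]
#' @export
destandardize <- function(est, transform) {
  stopifnot(inherits(est, "state_estimate"),
            inherits(transform, "standardization"))
  x <- transform$center + transform$scale * est$x
  V <- est$V * outer(transform$scale, transform$scale)
  state_estimate(x, V, layout = est$layout, pseudo = est$pseudo,
                 n = est$n, validate = FALSE)
}

#' Expand categorical variables into binary indicator names
#'
#' Multinomial auxiliary layers enter the state vector as one binary
#' indicator per category (e.g., an annual three-category damage-survey
#' classification over 19 years yields 57 indicators).  `cross_with_binary`
#' intersects a set of indicators with a two-level mask (e.g., a forest /
#' non-forest cover classification), doubling the count.
#'
#' @param series character vector of variable labels (e.g., years)
#' @param categories character vector of category labels
#' @return character vector of `length(series) * length(categories)` names
#' @examples
#' length(expand_multinomial(1999:2012, c("mortality", "surveyed", "unobserved")))
#' @export
expand_multinomial <- function(series, categories) {
  if (length(series) == 0L || length(categories) == 0L) return(character())
  as.vector(t(outer(as.character(series), as.character(categories), paste,
                    sep = ".")))
}

#' @rdname expand_multinomial
#' @param vars character vector of indicator names
#' @param mask_levels two labels for the binary mask
#' @export
cross_with_binary <- function(vars, mask_levels = c("in", "out")) {
  if (length(mask_levels) != 2L) stop("mask must have exactly two levels")
  as.vector(t(outer(as.character(vars), as.character(mask_levels), paste,
                    sep = ".")))
}
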