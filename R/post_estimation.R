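# Synthetic / pseudo estimators: post-estimation transformations of the
# state vector with delta-method covariance propagation.

#' Specify a post-estimation transformation
#'
#' Analysts need transformations of population estimates -- marginal sums of
#' table cells, differences, proportions such as the infested fraction of
#' live trees, rates such as annual mortality -- together with valid
#' variance estimates.  Each transform becomes a new "pseudo" state
#' variable appended to the state vector, with its variance and its
#' covariances with every existing state variable propagated from the full
#' state covariance matrix.  Because the output joins the state,
#' transformations chain: a later spec may reference an earlier output.
#'
#' @param op one of `"add"` (sum of the operands), `"subtract"`,
#'   `"multiply"`, `"divide"` (the last three take exactly two operands), or
#'   `"linear_combination"` (requires `coefficients`)
#' @param operands indices into the current state vector (including
#'   previously appended pseudo variables), or state-variable names
#' @param name name of the new pseudo variable
#' @param coefficients numeric vector, one per operand, for
#'   `"linear_combination"`
#' @return an object of class `transform_spec`
#' @export
transform_spec <- function(op = c("add", "subtract", "multiply", "divide",
                                  "linear_combination"),
                           operands, name, coefficients = NULL) {
  op <- match.arg(op)
  if (op %in% c("subtract", "multiply", "divide") && length(operands) != 2L) {
    stop("'", op, "' takes exactly two operands")
  }
  if (op == "linear_combination") {
    if (is.null(coefficients) || length(coefficients) != length(operands)) {
      stop("linear_combination needs one coefficient per operand")
    }
  }
  structure(list(op = op, operands = operands, name = as.character(name),
                 coefficients = coefficients),
            class = "transform_spec")
}

resolve_operands <- function(est, operands) {
  if (is.character(operands)) {
    idx <- match(operands, names(est$x))
    if (anyNA(idx)) {
      stop("unknown state variable(s): ",
           paste(operands[is.na(idx)], collapse = ", "))
    }
    idx
  } else {
    idx <- as.integer(operands)
    if (any(idx < 1L | idx > length(est$x))) {
      stop("operand index out of range")
    }
    idx
  }
}

#' Append a synthetic / pseudo estimate to the state
#'
#' Computes the transform's value and propagates uncertainty by a
#' first-order Taylor expansion: for gradient `g` the new variance is
#' `g' V g` and the covariance with the existing state is `V g`.  Linear
#' transforms (`add`, `subtract`, `linear_combination`) are exact; products
#' and ratios are first-order approximations, accurate when coefficients of
#' variation are small.  Appended pseudo variables may be used as operands
#' of later transforms but are never fed back into the Kalman update.
#'
#' @param est a [state_estimate()]
#' @param spec a [transform_spec()]
#' @return a [state_estimate()] of dimension `k + 1` whose last entry is the
#'   new pseudo variable
#' @examples
#' lay <- state_layout(c("infested", "live"), 1, character())
#' est <- state_estimate(c(2, 4), matrix(c(.04, .02, .02, .16), 2), lay)
#' out <- append_pseudo_estimate(
#'   est, transform_spec("divide", c(1, 2), "infested_fraction"))
#' out$x["infested_fraction"]         # 0.5
#' diag(out$V)["infested_fraction"]   # 0.00375
#' @export
append_pseudo_estimate <- function(est, spec) {
  stopifnot(inherits(est, "state_estimate"), inherits(spec, "transform_spec"))
  idx <- resolve_operands(est, spec$operands)
  x <- est$x
  k <- length(x)
  g <- numeric(k)
  value <- switch(spec$op,
    add = {
      g[idx] <- 1
      sum(x[idx])
    },
    subtract = {
      g[idx[1L]] <- g[idx[1L]] + 1
      g[idx[2L]] <- g[idx[2L]] - 1
      x[idx[1L]] - x[idx[2L]]
    },
    multiply = {
      g[idx[1L]] <- g[idx[1L]] + x[idx[2L]]
      g[idx[2L]] <- g[idx[2L]] + x[idx[1L]]
      x[idx[1L]] * x[idx[2L]]
    },
    divide = {
      den <- x[idx[2L]]
      if (den == 0) {
        stop("transform '", spec$name, "': denominator estimate is zero")
      }
      g[idx[1L]] <- g[idx[1L]] + 1 / den
      g[idx[2L]] <- g[idx[2L]] - x[idx[1L]] / den^2
      x[idx[1L]] / den
    },
    linear_combination = {
      for (j in seq_along(idx)) {
        g[idx[j]] <- g[idx[j]] + spec$coefficients[j]
      }
      sum(spec$coefficients * x[idx])
    })

  cov_new <- as.vector(est$V %*% g)
  var_new <- sum(g * cov_new)
  V <- rbind(cbind(est$V, cov_new), c(cov_new, var_new))
  x2 <- c(x, value)
  nm <- c(names(est$x), spec$name)
  names(x2) <- nm
  dimnames(V) <- list(nm, nm)
  state_estimate(x2, V, layout = est$layout,
                 pseudo = c(est$pseudo, spec$name), n = est$n,
                 validate = FALSE)
}

#' Population-level mortality rate
#'
#' In a rotating panel design the same tree is never measured in two
#' consecutive years, so an annual mortality rate is only estimable at the
#' population level: the number of live infested trees at time `t` divided
#' by the number of recent mortality trees at time `t + 1`.  A convenience
#' wrapper over [append_pseudo_estimate()] with the `divide` operator.
#'
#' @param est a [state_estimate()]
#' @param idx_infested_t state index (or name) of the live-infested count at
#'   time `t`
#' @param idx_mortality_t1 state index (or name) of the mortality count at
#'   time `t + 1`
#' @param name name for the appended rate
#' @return a [state_estimate()] of dimension `k + 1`
#' @export
mortality_rate <- function(est, idx_infested_t, idx_mortality_t1,
                           name = "mortality_rate") {
  append_pseudo_estimate(
    est,
    transform_spec("divide", c(idx_infested_t, idx_mortality_t1), name)
  )
}
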