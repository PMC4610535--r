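# The double-sum definition of the covariance of the SRS mean, used as an
# independent oracle against the cov()/n implementation.
srs_oracle <- function(X) {
  n <- nrow(X)
  xbar <- colMeans(X)
  S <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(n)) {
    d <- X[i, ] - xbar
    S <- S + tcrossprod(d)
  }
  S / (n - 1) / n
}

test_that("SRS estimate is the vector mean with covariance-of-the-mean", {
  lay <- state_layout("y", 1, "a")
  s <- data.frame(unit_id = 1:3, panel = 1,
                  y.1 = c(0, 2, 4), a = c(2, 4, 6), check.names = FALSE)
  est <- srs_estimate(s, lay)
  expect_equal(unname(est$x), c(2, 4))
  expect_equal(unname(est$V), matrix(4 / 3, 2, 2))
  expect_equal(est$n, 3)

  # identical rows carry no dispersion
  s0 <- data.frame(unit_id = 1:4, panel = 1, y.1 = 7, a = 1)
  expect_equal(unname(srs_estimate(s0, lay)$V), matrix(0, 2, 2))

  expect_error(srs_estimate(s[1, ], lay), "2 sampled units")
})

test_that("SRS covariance equals the literal double-sum oracle", {
  lay <- state_layout(c("u", "v"), times = 1:2, "a")
  for (seed in 1:10) {
    s <- random_sample_table(lay, n = 17, seed = seed)
    est <- srs_estimate(s, lay)
    X <- as.matrix(s[, state_names(lay)])
    expect_lt(max(abs(est$V - srs_oracle(X))), 1e-12)
  }
})

test_that("exact duplication of the sample rescales V by (n-1)/(2n-1)", {
  lay <- state_layout("u", 1, "a")
  s <- random_sample_table(lay, n = 9, seed = 3)
  est1 <- srs_estimate(s, lay)
  s2 <- rbind(s, s)
  s2$unit_id <- seq_len(nrow(s2))
  est2 <- srs_estimate(s2, lay)
  n <- nrow(s)
  # same mean; V scales by the exact algebraic factor (n-1)/(2n-1), the
  # 1/n shrinkage adjusted for the n/(n-1) covariance divisor
  expect_equal(est2$x, est1$x)
  expect_equal(est2$V, est1$V * (n - 1) / (2 * n - 1))
})

test_that("census constants are exact population means", {
  lay <- state_layout("s", 1, "a")
  pop <- data.frame(s.1 = c(9, 9), a = c(0, 1))
  expect_equal(unname(enumerate_census(pop, lay)$y), 0.5)
  expect_equal(unname(enumerate_census(data.frame(s.1 = 1:5, a = 3), lay)$y), 3)

  # binary layer: the mean is the class proportion, checked by counting
  set.seed(11)
  b <- rbinom(1000, 1, 0.3)
  cc <- enumerate_census(data.frame(s.1 = 0, a = b), lay)
  expect_equal(unname(cc$y), sum(b == 1) / length(b))
  expect_equal(cc$N, 1000)

  expect_error(enumerate_census(data.frame(s.1 = numeric(), a = numeric()),
                                lay), "empty")
})

test_that("eligibility requires min_nonzero at every time step", {
  lay <- state_layout(c("common", "rare"), times = 1:2, "aux_ok")
  n <- 60
  tab <- data.frame(
    unit_id = seq_len(n), panel = 1,
    common.1 = 1, common.2 = 1,
    rare.1 = rep(c(1, 0), c(25, n - 25)),    # passes at t1
    rare.2 = rep(c(1, 0), c(24, n - 24)),    # fails at t2 -> dropped whole
    aux_ok = rep(c(2, 0), c(25, n - 25)),
    check.names = FALSE
  )
  flt <- eligibility_filter(tab, lay, min_nonzero = 25)
  expect_setequal(flt$layout$study, "common")
  expect_setequal(flt$layout$aux, "aux_ok")
  expect_equal(sort(c(flt$kept, flt$dropped)), seq_len(lay$k))

  # boundary: exactly 25 nonzero is kept, 24 is not
  tab$aux_ok <- rep(c(2, 0), c(24, n - 24))
  expect_length(eligibility_filter(tab, lay, 25)$layout$aux, 0)

  # all-zero variable dropped regardless of n
  tab$aux_ok <- 0
  expect_length(eligibility_filter(tab, lay, 1)$layout$aux, 0)
})

test_that("eligibility is monotone in the threshold", {
  lay <- state_layout("s", 1, paste0("a", 1:6))
  set.seed(5)
  X <- matrix(rbinom(40 * 7, 1, 0.4), 40, 7)
  colnames(X) <- state_names(lay)
  tab <- data.frame(unit_id = 1:40, panel = 1, X, check.names = FALSE)
  kept_prev <- NULL
  for (m in c(5, 10, 15, 20, 25)) {
    kept <- eligibility_filter(tab, lay, m)$kept
    if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})

test_that("panel pooling selects the moving window of panels", {
  lay <- state_layout("s", times = 2002:2012)
  tab <- data.frame(unit_id = 1:11, panel = 2002:2012,
                    matrix(1, 11, lay$k,
                           dimnames = list(NULL, state_names(lay))),
                    check.names = FALSE)
  w <- pool_panels(tab, lay, anchor_time = 2004, window = 3)
  expect_setequal(w$panel, 2002:2004)

  expect_equal(pool_panels(tab, lay, 2003, window = 1)$panel, 2003)
  # truncated at the series edge
  expect_setequal(pool_panels(tab, lay, 2002, window = 3)$panel, 2002)
  expect_setequal(pool_panels(tab, lay, 2003, window = 3,
                              align = "centered")$panel, 2002:2004)
  expect_error(pool_panels(tab, lay, 2003, window = 0), "window")
})

# Textbook post-stratified variance for a single variable, computed directly.
poststrat_oracle <- function(x, strat, W) {
  n <- length(x)
  s2 <- tapply(x, strat, var)[names(W)]
  sum(W * s2) / n + sum((1 - W) * s2) / n^2
}

test_that("post-stratification with one stratum reduces to SRS", {
  lay <- state_layout(c("u", "v"), 1)
  s <- random_sample_table(lay, n = 30, seed = 9)
  s$stratum <- "all"
  ps <- poststratified_estimate(s, lay, c(all = 1), min_per_stratum = 10)
  est <- srs_estimate(s, lay)
  expect_equal(ps$mean, unname(est$x))
  expect_equal(ps$variance, unname(diag(est$V)))
  expect_false(attr(ps, "fallback"))
})

test_that("post-stratified variance matches the direct formula", {
  lay <- state_layout("u", 1)
  set.seed(21)
  s <- random_sample_table(lay, n = 40, seed = 21)
  s$stratum <- rep(c("A", "B"), each = 20)
  s$u.1 <- s$u.1 + ifelse(s$stratum == "A", 0, 5)
  W <- c(A = 0.5, B = 0.5)
  ps <- poststratified_estimate(s, lay, W, min_per_stratum = 10)
  expect_equal(ps$variance,
               unname(poststrat_oracle(s$u.1, s$stratum, W)))
  mu <- tapply(s$u.1, s$stratum, mean)
  expect_equal(ps$mean, unname(sum(W * mu[names(W)])))

  # zero within-stratum variance gives (near) zero estimator variance
  s$u.1 <- ifelse(s$stratum == "A", 1, 3)
  ps0 <- poststratified_estimate(s, lay, W, min_per_stratum = 10)
  expect_equal(ps0$variance, 0)
})

test_that("small strata collapse per the merge order, else fall back to SRS", {
  lay <- state_layout("u", 1)
  s <- random_sample_table(lay, n = 30, seed = 13)
  s$stratum <- rep(c("mort_forest", "mort", "clean"), c(4, 11, 15))
  W <- c(mort_forest = 0.1, mort = 0.3, clean = 0.6)
  ps <- poststratified_estimate(s, lay, W, min_per_stratum = 10,
                                collapse_map = c(mort_forest = "mort"))
  expect_equal(attr(ps, "merges"), "mort_forest -> mort")
  expect_false(attr(ps, "fallback"))
  # merged stratum weight is the sum of the two
  merged <- factor(ifelse(s$stratum == "mort_forest", "mort", s$stratum))
  expect_equal(ps$variance,
               unname(poststrat_oracle(s$u.1, as.character(merged),
                                       c(mort = 0.4, clean = 0.6))))

  # no applicable merge: falls back to SRS and flags it
  ps2 <- poststratified_estimate(s, lay, W, min_per_stratum = 10,
                                 collapse_map = NULL)
  est <- srs_estimate(s, lay)
  expect_true(attr(ps2, "fallback"))
  expect_equal(ps2$mean, unname(est$x))
})

test_that("design effect is the percent variance reduction against SRS", {
  expect_equal(design_effect(0.9, 1.0), 10)
  expect_equal(design_effect(1, 1), 0)
  expect_equal(design_effect(1.2, 1.0), -20)
  expect_equal(design_effect(c(0.5, 2), c(1, 1)), c(50, -100))
  expect_error(design_effect(1, 0), "positive")
})
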