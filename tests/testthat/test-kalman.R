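off <- kf_options(divergence = "off")

test_that("a single constraint reproduces the conditional-normal closed form", {
  lay <- state_layout("s", 1, "a")
  est <- state_estimate(c(1, 2), matrix(c(1, .5, .5, 1), 2), lay)
  res <- kf_sequential(est, census_constants(c(a = 3), lay), off)
  expect_equal(unname(res$estimate$x), c(1.5, 3.0))
  expect_equal(unname(res$estimate$V),
               matrix(c(1 - 0.5^2, 0, 0, 0), 2))
  expect_equal(res$audit$status, "applied")

  # one scalar step does the same
  one <- scalar_step(est, 1, 3)
  expect_equal(one$x, res$estimate$x)
  expect_equal(one$V, res$estimate$V)

  # and the batch closed form agrees
  b <- kf_batch(est, c(3))
  expect_equal(b$x, res$estimate$x)
  expect_equal(b$V, res$estimate$V, tolerance = 1e-12)
})

test_that("zero study-auxiliary covariance leaves the study variable alone", {
  lay <- state_layout("s", 1, "a")
  est <- state_estimate(c(1, 2), diag(2), lay)
  res <- kf_sequential(est, c(5), off)
  expect_equal(unname(res$estimate$x), c(1, 5))
  expect_equal(res$estimate$V[1, 1], 1)
  expect_equal(res$estimate$V[2, 2], 0)
})

test_that("an auxiliary with variance below tol is skipped untouched", {
  lay <- state_layout("s", 1, "a")
  est <- state_estimate(c(1, 2), diag(c(1, 1e-6)), lay)
  res <- kf_sequential(est, c(5), kf_options(tol = 1e-4, divergence = "off"))
  expect_equal(res$audit$status, "skipped_low_variance")
  expect_equal(res$estimate$x, est$x)
  expect_equal(res$estimate$V, est$V)

  # re-applying an already-applied constraint is a no-op via the same skip
  est2 <- state_estimate(c(1, 2), matrix(c(1, .4, .4, 1), 2), lay)
  first <- kf_sequential(est2, c(5), off)
  second <- kf_sequential(first$estimate, c(5),
                          kf_options(tol = 1e-12, divergence = "off"))
  expect_equal(second$audit$status, "skipped_low_variance")
  expect_equal(second$estimate$x, first$estimate$x)
})

test_that("divergence inflation follows the printed rule and the 2-sigma rule", {
  lay <- state_layout("s", 1, "a")
  V <- matrix(c(1, .3, .3, .5), 2)
  est <- state_estimate(c(0, 0), V, lay)

  # printed rule: c = 2|y - x|/V_kk = 4 > 1, row/col scaled by c
  infl <- divergence_inflate(est, 1, 1, mode = "as_printed")
  expect_equal(infl$c, 4)
  expect_equal(infl$estimate$V[2, 2], 0.5 * 16)     # diagonal by c^2
  expect_equal(infl$estimate$V[1, 2], 0.3 * 4)
  expect_equal(infl$estimate$V[1, 1], 1)            # other rows untouched

  # below the trigger nothing happens
  none <- divergence_inflate(est, 1, 0.1, mode = "as_printed")
  expect_true(is.na(none$c))
  expect_equal(none$estimate$V, est$V)

  # 2-sigma rule: residual 3 with unit variance -> post-inflation SD 1.5
  est2 <- state_estimate(c(0, 0), diag(2), lay)
  two <- divergence_inflate(est2, 1, 3, mode = "two_sigma")
  expect_equal(sqrt(two$estimate$V[2, 2]), 1.5)
  # residual is exactly two post-inflation SDs
  expect_equal(3 / sqrt(two$estimate$V[2, 2]), 2)

  # the full update records the inflation in the audit
  res <- kf_sequential(est, c(1), kf_options(divergence = "as_printed"))
  expect_equal(res$audit$status, "inflated_then_applied")
  expect_equal(res$audit$c, 4)
  # the constraint is still exact after inflation
  expect_equal(unname(res$estimate$x[2]), 1)
})

test_that("sequential update equals the batch closed form on random problems", {
  opts <- kf_options(tol = 0, divergence = "off")
  for (trial in 1:200) {
    k_a <- sample(1:6, 1)
    k_s <- sample(1:14, 1)
    est <- random_psd_estimate(k_s, k_a, seed = trial)
    census <- random_census(est$layout, seed = 1000 + trial)
    seq_res <- kf_sequential(est, census, opts)$estimate
    bat <- kf_batch(est, census)
    scale_x <- max(abs(bat$x), 1)
    scale_v <- max(abs(bat$V), 1)
    expect_lt(max(abs(seq_res$x - bat$x)) / scale_x, 1e-8)
    expect_lt(max(abs(seq_res$V - bat$V)) / scale_v, 1e-8)
  }
})

test_that("constraints are exact and orthogonalised, variances never grow", {
  for (seed in 1:25) {
    est <- random_psd_estimate(k_s = 5, k_a = 4, seed = seed)
    census <- random_census(est$layout, seed = 500 + seed)
    res <- kf_sequential(est, census, off)$estimate
    aidx <- selection_indices(est$layout)
    expect_identical(unname(res$x[aidx]), unname(census$y))
    expect_identical(unname(res$V[aidx, ]), matrix(0, 4, est$layout$k))
    expect_identical(unname(res$V[, aidx]), matrix(0, est$layout$k, 4))
    expect_true(all(diag(res$V) <= diag(est$V) + 1e-12))
  }
})

test_that("the diagonal is non-increasing across every scalar step", {
  est <- random_psd_estimate(k_s = 4, k_a = 4, seed = 77)
  census <- random_census(est$layout, seed = 78)
  cur <- est
  for (i in 4:1) {
    nxt <- scalar_step(cur, i, census$y[i])
    expect_true(all(diag(nxt$V) <= diag(cur$V) + 1e-12))
    cur <- nxt
  }
})

test_that("processing order does not change the final estimate", {
  for (seed in 1:25) {
    est <- random_psd_estimate(k_s = 3, k_a = 5, seed = seed)
    census <- random_census(est$layout, seed = 300 + seed)
    down <- kf_sequential(est, census,
                          kf_options(tol = 0, divergence = "off"))$estimate
    up <- kf_sequential(est, census,
                        kf_options(tol = 0, divergence = "off",
                                   order = "ascending"))$estimate
    expect_lt(max(abs(down$x - up$x)) / max(abs(down$x), 1), 1e-8)
    expect_lt(max(abs(down$V - up$V)) / max(abs(down$V), 1), 1e-8)
  }
})

test_that("updating in standardized space and transforming back is the same", {
  opts <- kf_options(tol = 0, divergence = "off")
  for (seed in 1:25) {
    est <- random_psd_estimate(k_s = 4, k_a = 3, seed = seed)
    census <- random_census(est$layout, seed = 700 + seed)
    direct <- kf_sequential(est, census, opts)$estimate
    via_std <- kf_estimate(est, census, opts)$estimate
    expect_lt(max(abs(direct$x - via_std$x)) / max(abs(direct$x), 1), 1e-8)
    expect_lt(max(abs(direct$V - via_std$V)) / max(abs(direct$V), 1), 1e-8)
  }
})

test_that("a duplicated auxiliary column is skipped, not double-counted", {
  lay1 <- state_layout(c("s1", "s2"), 1, "a")
  set.seed(91)
  X <- matrix(rnorm(60 * 3), 60, 3)
  colnames(X) <- state_names(lay1)
  tab1 <- data.frame(unit_id = 1:60, panel = 1, X, check.names = FALSE)
  est1 <- srs_estimate(tab1, lay1)
  res1 <- kf_sequential(est1, c(0.1), off)

  lay2 <- state_layout(c("s1", "s2"), 1, c("a", "a_copy"))
  tab2 <- tab1
  tab2$a_copy <- tab2$a
  est2 <- srs_estimate(tab2, lay2)
  res2 <- kf_sequential(est2, c(0.1, 0.1), off)

  expect_equal(unname(res2$estimate$x[1:2]), unname(res1$estimate$x[1:2]),
               tolerance = 1e-8)
  expect_equal(unname(res2$estimate$V[1:2, 1:2]),
               unname(res1$estimate$V[1:2, 1:2]), tolerance = 1e-8)
  expect_true("skipped_low_variance" %in% res2$audit$status)
})

test_that("the updated covariance stays positive semidefinite", {
  for (seed in 1:20) {
    est <- random_psd_estimate(k_s = 6, k_a = 4, seed = seed)
    census <- random_census(est$layout, seed = 900 + seed)
    for (mode in c("off", "as_printed", "two_sigma")) {
      res <- kf_sequential(est, census, kf_options(divergence = mode))
      V <- res$estimate$V
      ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * max(diag(V)))
    }
  }
})

test_that("malformed inputs are rejected", {
  lay <- state_layout("s", 1, "a")
  est <- state_estimate(c(1, 2), diag(2), lay)
  expect_error(kf_sequential(est, c(1, 2), off), "length")
  expect_error(kf_sequential(est, c(NaN), off), "non-finite")

  # pseudo variables must not re-enter the filter
  withps <- append_pseudo_estimate(
    est, transform_spec("add", c(1, 2), "total"))
  expect_error(kf_sequential(withps, c(1), off), "pseudo")

  # batch form needs an invertible auxiliary block unless told otherwise
  lay2 <- state_layout("s", 1, c("a1", "a2"))
  Vs <- matrix(0.5, 3, 3); diag(Vs) <- 1
  Vs[2, 3] <- Vs[3, 2] <- 1   # aux block singular
  est2 <- state_estimate(c(0, 0, 0), Vs, lay2, validate = FALSE)
  expect_error(kf_batch(est2, c(1, 1)), "singular")
  ok <- kf_batch(est2, c(1, 1), pseudo_inverse = TRUE)
  expect_equal(unname(ok$x[2:3]), c(1, 1))
})

test_that("no auxiliary block means the update is the identity", {
  lay <- state_layout(c("u", "v"), 1)
  est <- state_estimate(c(1, 2), diag(2), lay)
  expect_equal(kf_batch(est, numeric())$x, est$x)
  res <- kf_sequential(est, numeric(), off)
  expect_equal(res$estimate$x, est$x)
  expect_equal(nrow(res$audit), 0)
})
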