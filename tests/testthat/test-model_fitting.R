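test_that("cubic inversions recover the bond parameters", {
  expect_equal(solve_x_given(3, u = 1, m = 1), 1.0, tolerance = 1e-9)
  expect_equal(solve_y_given(3, u = 1), 1.0, tolerance = 1e-9)
  # published 23 bp data: x ~ 1.7, y ~ 5.0 at u = 4.6
  expect_equal(solve_x_given(12.6, 4.6, 11), 1.705, tolerance = 1e-3)
  expect_equal(solve_y_given(29.6, 4.6), 5.016, tolerance = 1e-3)
  # 33 bp data (1.6196 verified independently by polyroot and bisection)
  expect_equal(solve_x_given(20.1, 4.6, 21), 1.6196, tolerance = 1e-3)
  expect_equal(solve_y_given(30.8, 4.6), 5.083, tolerance = 1e-3)
})

test_that("inversion round-trips the closed forms", {
  set.seed(17)
  for (i in 1:50) {
    x <- runif(1, 0.5, 8); y <- runif(1, 0.5, 8); u <- runif(1, 0.1, 50)
    m <- sample(1:50, 1)
    p <- suppressWarnings(rate_params(x, y, u))
    expect_equal(solve_x_given(lifetime_nn(p, m), u, m), x, tolerance = 1e-9)
    expect_equal(solve_y_given(lifetime_ss(p), u), y, tolerance = 1e-9)
  }
})

test_that("fit_params recovers exactly-solvable triples from any start", {
  p0 <- rate_params(2, 4, 3)
  triple <- lifetime_triple(lifetime_nn(p0, 11), lifetime_ss(p0),
                            lifetime_ns(p0, 11), m = 11)
  for (seed in c(1, 2, 3)) {
    mf <- fit_params(triple, seed = seed)
    expect_equal(mf$params$x, 2, tolerance = 1e-6)
    expect_equal(mf$params$y, 4, tolerance = 1e-6)
    expect_equal(mf$params$u, 3, tolerance = 1e-6)
    expect_lt(max(abs(mf$residuals)), 1e-8)
  }
  # objective choice does not matter when a zero-residual solution exists
  mfa <- fit_params(triple, objective = "absolute")
  expect_equal(mfa$params$x, 2, tolerance = 1e-6)
})

test_that("noisy triples are fitted at least as well as the generating
          parameters", {
  # the (x, y, u) -> lifetimes map has log-log condition number ~300 here,
  # so parameter recovery under noise is intrinsically poor (see the
  # vignette); the provable property is that the optimizer's objective is
  # no worse than the objective evaluated at the true parameters, and that
  # residuals stay at the noise scale
  set.seed(5)
  for (i in 1:10) {
    p0 <- suppressWarnings(rate_params(runif(1, 1.2, 3), runif(1, 2, 8),
                                       runif(1, 1, 10)))
    eps <- rnorm(3, 0, 0.03)
    noisy <- lifetime_triple(lifetime_nn(p0, 11) * exp(eps[1]),
                             lifetime_ss(p0) * exp(eps[2]),
                             lifetime_ns(p0, 11) * exp(eps[3]),
                             m = 11)
    mf <- fit_params(noisy, n_starts = 8)
    # relative residual of the true params against the noisy data is
    # (1/exp(eps) - 1) per equation
    value_at_truth <- sum((exp(-eps) - 1)^2)
    expect_lte(mf$value, value_at_truth + 1e-10)
    expect_lt(max(abs(mf$residuals)), 0.1)
  }
})

test_that("the published 23 bp data admit no exact solution; the profile ns
          prediction stays in the mid-30s", {
  mf <- fit_params(lifetime_triple(12.6, 29.6, 44.7, m = 11))
  expect_gt(abs(mf$residuals[["ns"]]), 0.05)  # irreducible ns misfit
  # profiled ns prediction at u = 4.6 is ~36.3 s, far from 44.7 s
  prof <- mf$profile
  at46 <- prof[which.min(abs(prof$u - 4.6)), ]
  expect_equal(at46$t_ns_pred, 36.3, tolerance = 0.01)
  # over the whole scanned u range the prediction never reaches 44.7 s
  expect_lt(max(prof$t_ns_pred), 40)
  expect_equal(at46$x, 1.705, tolerance = 1e-2)
  expect_equal(at46$y, 5.016, tolerance = 1e-2)
})

test_that("lifetime_report lines up predictions against measurements", {
  p <- published_params()
  configs <- list(complex_config("ss", 23), complex_config("ns", 23),
                  complex_config("nn", 23))
  rep <- lifetime_report(p, configs, experimental = c(29.6, 44.7, 12.6))
  expect_equal(nrow(rep), 3L)
  expect_lt(abs(rep$rel_deviation[rep$kind == "ss"]), 0.01)
  expect_equal(rep$rel_deviation[rep$kind == "ns"], -0.194, tolerance = 0.01)
  expect_lt(abs(rep$rel_deviation[rep$kind == "nn"]), 0.01)
  expect_equal(attr(rep, "Es_kT"), 2 * log(5))
  expect_error(lifetime_report(p, configs, experimental = 1:2), "length")
})

test_that("weighted fitting validates its SDs", {
  tr <- lifetime_triple(12.6, 29.6, 44.7, m = 11)
  expect_error(fit_params(tr, weighted = TRUE), "SDs")
  tr2 <- lifetime_triple(12.6, 29.6, 44.7, m = 11,
                         sd_nn = 0.2, sd_ss = 0.4, sd_ns = 0.8)
  mf <- fit_params(tr2, weighted = TRUE, n_starts = 8)
  expect_s3_class(mf, "model_fit")
})
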