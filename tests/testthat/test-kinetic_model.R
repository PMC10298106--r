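test_that("multiplicity counts binding registers and rejects bad geometry", {
  expect_identical(multiplicity(23, 13), 11L)
  expect_identical(multiplicity(13, 13), 1L)   # footprint fills the duplex
  expect_identical(multiplicity(33, 13), 21L)
  expect_error(multiplicity(12, 13), "12.*13")  # names both values
  expect_error(multiplicity(23, 0), "footprint")
})

test_that("rate_params validates and warns on sub-unity bond parameters", {
  p <- rate_params(1.7, 5.0, 4.6)
  expect_s3_class(p, "rate_params")
  expect_error(rate_params(-1, 5, 4.6), "positive")
  expect_error(rate_params(1.7, 5, 0), "positive")
  expect_warning(rate_params(0.5, 5, 1), "negative bond energy")
})

test_that("bond_rates implements u/x, m*u*x, u/y, u*y and detailed balance", {
  r0 <- bond_rates(rate_params(1, 1, 1), m = 1)
  expect_equal(unlist(r0), c(break_ns = 1, rebind_ns = 1,
                             break_s = 1, rebind_s = 1))
  r <- bond_rates(published_params(), m = 11)
  expect_equal(r$break_ns, 4.6 / 1.7, tolerance = 1e-12)
  expect_equal(r$rebind_ns, 11 * 4.6 * 1.7, tolerance = 1e-12)
  expect_equal(r$break_s, 0.92, tolerance = 1e-12)
  expect_equal(r$rebind_s, 23.0, tolerance = 1e-12)
  # single-bond equilibrium: (rebind/m)/break = x^2 for random params
  set.seed(1)
  for (i in 1:20) {
    x <- runif(1, 0.5, 10); m <- sample(1:50, 1)
    p <- suppressWarnings(rate_params(x, runif(1, 0.5, 10), runif(1, .1, 100)))
    rr <- bond_rates(p, m)
    expect_equal((rr$rebind_ns / m) / rr$break_ns, x^2, tolerance = 1e-10)
  }
})

test_that("closed-form lifetimes match hand-derived values", {
  p1 <- rate_params(1, 1, 1)
  expect_equal(lifetime_nn(p1, 1), 3)
  expect_equal(lifetime_ss(p1), 3)
  expect_equal(lifetime_ns(p1, 1), 3)
  p <- published_params()
  expect_equal(lifetime_nn(p, 11), (2 * 1.7 + 11 * 1.7^3) / 4.6)   # 12.49
  expect_equal(lifetime_nn(p, 21), (2 * 1.7 + 21 * 1.7^3) / 4.6)   # 23.17
  expect_equal(lifetime_ss(p), 135 / 4.6)                          # 29.35
  expect_equal(lifetime_ns(p, 11), (1.7 + 5 + 11 * 1.7^2 * 5) / 4.6)
  expect_equal(lifetime_ns(p, 21), (6.7 + 21 * 1.7^2 * 5) / 4.6)   # 67.43
})

test_that("closed forms equal the first-step-analysis oracle", {
  # 1000 random parameter sets, all three complex kinds
  set.seed(20230606)
  for (i in 1:1000) {
    x <- runif(1, 0.5, 10); y <- runif(1, 0.5, 10)
    u <- runif(1, 0.1, 100); m <- sample(1:50, 1)
    p <- suppressWarnings(rate_params(x, y, u))
    r <- bond_rates(p, m)
    expect_equal(mfpt_oracle(r$break_ns, r$rebind_ns, r$break_ns),
                 lifetime_nn(p, m), tolerance = 1e-10)
    expect_equal(mfpt_oracle(r$break_s, r$rebind_s, r$break_s),
                 lifetime_ss(p), tolerance = 1e-10)
    expect_equal(mfpt_oracle(r$break_ns, r$rebind_ns, r$break_s),
                 lifetime_ns(p, m), tolerance = 1e-10)
  }
})

test_that("mfpt_oracle handles degenerate rates", {
  expect_equal(mfpt_oracle(1, 1, 1), 3)
  expect_equal(mfpt_oracle(2, 0, 5), 1 / 2 + 1 / 5)  # irreversible chain
  expect_error(mfpt_oracle(0, 1, 1), "absorb")
  expect_error(mfpt_oracle(1, 1, 0), "absorb")
  expect_error(mfpt_oracle(1, -1, 1), ">= 0")
})

test_that("lifetimes are monotone in multiplicity; ss is constant", {
  p <- published_params()
  nn <- vapply(1:30, function(m) lifetime_nn(p, m), numeric(1))
  ns <- vapply(1:30, function(m) lifetime_ns(p, m), numeric(1))
  expect_true(all(diff(nn) > 0))
  expect_true(all(diff(ns) > 0))
  expect_equal(predict_lifetime(p, complex_config("ss", 23))$lifetime,
               predict_lifetime(p, complex_config("ss", 33))$lifetime,
               ignore_attr = TRUE)
})

test_that("entropic crossover: T_ns > T_ss > T_nn at published parameters", {
  p <- published_params()
  expect_gt(lifetime_ns(p, 11), lifetime_ss(p))
  expect_gt(lifetime_ss(p), lifetime_nn(p, 11))
})

test_that("energy conversion is 2*ln(p) with exact round trip", {
  expect_equal(energy_from_param(1), 0)
  expect_equal(energy_from_param(5.0), 2 * log(5))      # ~3.22 kT
  expect_equal(energy_from_param(1.7), 2 * log(1.7))    # ~1.06 kT
  expect_error(energy_from_param(0), "> 0")
  p <- exp(seq(log(0.1), log(100), length.out = 50))
  expect_equal(param_from_energy(energy_from_param(p)), p, tolerance = 1e-12)
})

test_that("predict_lifetime dispatches on kind, lengths and designation", {
  p <- published_params()
  # ns with designated non-specific duplex picks that duplex's multiplicity
  pr23 <- predict_lifetime(p, complex_config("ns", 23, 33, nonspecific = "a"))
  expect_equal(unname(pr23$lifetime), lifetime_ns(p, 11))
  pr33 <- predict_lifetime(p, complex_config("ns", 23, 33, nonspecific = "b"))
  expect_equal(unname(pr33$lifetime), lifetime_ns(p, 21))
  # undesignated mixed ns reports both branches
  both <- predict_lifetime(p, complex_config("ns", 23, 33))
  expect_named(both$lifetime, c("ns_23bp", "ns_33bp"))
  expect_equal(unname(both$lifetime), c(lifetime_ns(p, 11), lifetime_ns(p, 21)))
  # mixed nn averages the pure-length lifetimes: x = 1 gives (13 + 23)/2
  pn <- predict_lifetime(rate_params(1, 1, 1), complex_config("nn", 23, 33))
  expect_equal(unname(pn$lifetime), 18)
  expect_error(complex_config("nn", 10, 23), "footprint")
})

test_that("prediction_table is tidy with one row per branch", {
  p <- published_params()
  tab <- prediction_table(p, list(complex_config("ss", 23),
                                  complex_config("ns", 23, 33),
                                  complex_config("nn", 23)))
  expect_equal(nrow(tab), 4L)  # ss, ns both branches, nn
  expect_setequal(names(tab),
                  c("kind", "length_a", "length_b", "branch", "m", "lifetime_s"))
  expect_equal(tab$m[tab$branch == "ns_33bp"], 21L)
  expect_true(all(tab$lifetime_s > 0))
})
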