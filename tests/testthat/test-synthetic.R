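test_that("harmonic ensemble matches its analytic per-window means", {
  m <- harmonic_model(1, 4, kT = kT300)
  expect_equal(m$dG_true, kT300 / 2 * log(4))

  sched <- lambda_schedule(c(0, 0.5, 1))
  sim <- harmonic_ti_ensemble(m, sched, ensemble_size = 4,
                              n_samples = 4000, seed = 2)
  for (lam in sched$values) {
    ser <- series_at_lambda(sim$gradients, lam)
    samp <- unlist(lapply(ser, function(s) s$samples))
    k <- (1 - lam) * 1 + lam * 4
    analytic <- (4 - 1) / 2 * kT300 / k
    # chi-square mean with sd ~ sqrt(2)*analytic/sqrt(n)
    expect_equal(mean(samp), analytic,
                 tolerance = 4 * sqrt(2) / sqrt(16000))
  }

  # degenerate transformation: identical stiffness gives zero gradients
  flat <- harmonic_model(2, 2, kT = kT300)
  simf <- harmonic_ti_ensemble(flat, sched, 2, 10, seed = 3)
  expect_equal(simf$dG_true, 0)
  expect_true(all(vapply(simf$gradients$series,
                         function(s) all(s$samples == 0), TRUE)))

  # bit reproducibility
  a <- harmonic_ti_ensemble(m, sched, 3, 20, seed = 9)
  b <- harmonic_ti_ensemble(m, sched, 3, 20, seed = 9)
  expect_identical(a$gradients$series[[5]]$samples,
                   b$gradients$series[[5]]$samples)
})

test_that("Gaussian work sets satisfy the Crooks construction", {
  ws <- gaussian_work_set(5, sqrt(2), 1e4, 1e4, 10, ctx_kT1, seed = 4)
  se <- sqrt(2) / sqrt(1e4)
  expect_equal(mean(forward_works(ws)), 6, tolerance = 3 * se)
  expect_equal(mean(reverse_works(ws)), -4, tolerance = 3 * se)
  expect_equal(sd(forward_works(ws)), sqrt(2), tolerance = 0.05)
  # even replica tagging
  expect_equal(unname(table(ws$records$replica_id)), rep(2000L, 10),
               ignore_attr = TRUE)

  # near-deterministic limit: bar_mle returns dG
  ws0 <- gaussian_work_set(5, 1e-8, 100, 100, 1, ctx_kT1, seed = 5)
  expect_equal(bar_mle(ws0, ctx_kT1)$value, 5, tolerance = 1e-6)

  expect_identical(
    gaussian_work_set(5, 1, 100, 100, 5, ctx_kT1, seed = 6)$records,
    gaussian_work_set(5, 1, 100, 100, 5, ctx_kT1, seed = 6)$records)

  expect_abfe_error(gaussian_work_set(5, 1, 101, 100, 10, ctx_kT1, 1),
                    "abfe_parameter_error")
})

test_that("OU switching has the right limits", {
  m <- harmonic_model(1, 4, kT = kT300)

  # quasi-static: total switching time = 100 * relax_time
  wq <- ou_switching_work(m, n_steps = 2000, dt = 1, relax_time = 20,
                          n_transitions = 400, "forward", seed = 8)
  expect_equal(mean(wq), m$dG_true, tolerance = 0.05 * m$dG_true)

  # instantaneous switch reproduces the FEP identity:
  # W = (k1-k0) x^2 / 2 with x from the initial equilibrium
  w1 <- ou_switching_work(m, n_steps = 1, dt = 1, relax_time = 20,
                          n_transitions = 5000, "forward", seed = 9)
  expect_equal(mean(w1), (4 - 1) / 2 * kT300 / 1,
               tolerance = 4 * sqrt(2) * (3 / 2) * kT300 / sqrt(5000))
  expect_true(all(w1 >= 0))

  wr1 <- ou_switching_work(m, n_steps = 1, dt = 1, relax_time = 20,
                           n_transitions = 5000, "reverse", seed = 10)
  expect_equal(mean(wr1), -(4 - 1) / 2 * kT300 / 4,
               tolerance = 4 * sqrt(2) * (3 / 8) * kT300 / sqrt(5000))

  # dissipation is non-negative on average and decreases with switching time
  diss <- vapply(c(20, 80, 320), function(ns) {
    w <- ou_switching_work(m, ns, 2, 20, 400, "forward", seed = 12)
    mean(w) - m$dG_true
  }, 0)
  expect_true(all(diss > -0.02))
  expect_true(all(diff(diss) < 0))

  # CFT validity: bidirectional MLE recovers dG_true at any switching speed
  ctxm <- thermo_context(m$kT / BOLTZMANN_KCAL)
  wf <- ou_switching_work(m, 50, 2, 20, 2000, "forward", seed = 13)
  wr <- ou_switching_work(m, 50, 2, 20, 2000, "reverse", seed = 14)
  ws <- make_work_set(wf, wr, rep(1:10, each = 200), rep(1:10, each = 200))
  est <- neq_free_energy(ws, ctxm)
  expect_lt(abs(est$value - m$dG_true), 3 * est$stderr)
})

test_that("extreme-value injection is exactly reversed by the filter", {
  ws <- gaussian_work_set(5, sqrt(2), 500, 500, 5, ctx_kT1, seed = 15)
  contaminated <- inject_extremes(ws, count = 3, magnitude = 1500,
                                  seed = 16)
  expect_equal(contaminated$meta$n_fwd, 503)
  f <- filter_extreme_work(contaminated)
  expect_equal(f$n_removed_fwd, 3)
  expect_equal(f$n_removed_rev, 0)
  expect_equal(sort(forward_works(f$filtered)), sort(forward_works(ws)))

  # count 0 is the identity
  expect_identical(inject_extremes(ws, 0, 1500, seed = 1)$records,
                   ws$records)

  # magnitudes at or below the filter cutoff are refused
  expect_abfe_error(inject_extremes(ws, 2, magnitude = 900, seed = 1),
                    "abfe_parameter_error")

  # filtering restores the estimate; the contaminated one is shifted
  clean <- bar_mle(ws, ctx_kT1)
  filtered <- bar_mle(f$filtered, ctx_kT1)
  dirty <- bar_mle(contaminated, ctx_kT1)
  expect_lt(abs(filtered$value - clean$value), 1e-10)
  expect_gt(abs(dirty$value - clean$value), 0)
})

test_that("skew-normal ensembles reproduce the analytic skewness", {
  x0 <- skewed_dg_ensemble(0, 1, 0, 1e5, seed = 17)
  expect_lt(abs(moment_diagnostics(x0)$skewness), 0.05)
  expect_equal(attr(x0, "analytic_skewness"), 0)

  x5 <- skewed_dg_ensemble(-8, 1.5, 5, 1e5, seed = 18)
  expect_equal(moment_diagnostics(as.numeric(x5))$skewness,
               attr(x5, "analytic_skewness"), tolerance = 0.05)

  # mirroring flips the skewness sign
  mirrored <- moment_diagnostics(-as.numeric(x5))
  expect_equal(mirrored$skewness,
               -moment_diagnostics(as.numeric(x5))$skewness)

  expect_identical(as.numeric(skewed_dg_ensemble(0, 1, 2, 50, seed = 19)),
                   as.numeric(skewed_dg_ensemble(0, 1, 2, 50, seed = 19)))
})
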