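test_that("work integration follows the lambda path and its orientation", {
  n <- 11
  s_const <- gradient_series(1, 0.5, rep(3.5, n), times = seq_len(n))
  expect_equal(integrate_work(s_const, seq(0, 1, length.out = n)), 3.5)
  expect_equal(integrate_work(s_const, seq(1, 0, length.out = n)), -3.5)

  # integral of 2*lambda over [0,1] = 1
  lam <- seq(0, 1, length.out = 2001)
  s_lin <- gradient_series(1, 0.5, 2 * lam, times = seq_along(lam))
  expect_equal(integrate_work(s_lin, lam), 1.0, tolerance = 1e-3)

  expect_abfe_error(integrate_work(s_const, c(seq(0, 1, length.out = n - 1), 0.5)),
                    "abfe_domain_error")
  expect_abfe_error(integrate_work(s_const, seq(0, 1, length.out = n + 2)),
                    "abfe_format_error")
})

test_that("extreme-work filter removes exactly the values above cutoff", {
  ws <- make_work_set(c(3.2, 1500.0, -7.1), c(-1, -2))
  f <- filter_extreme_work(ws)
  expect_equal(f$n_removed_fwd, 1)
  expect_equal(f$n_removed_rev, 0)
  expect_equal(sort(forward_works(f$filtered)), c(-7.1, 3.2))

  # identity when nothing exceeds the cutoff, and idempotence
  clean <- make_work_set(c(1, 2, 3), c(-1, -2))
  f1 <- filter_extreme_work(clean)
  expect_equal(f1$n_removed_fwd + f1$n_removed_rev, 0)
  expect_equal(f1$filtered$records, clean$records)
  f2 <- filter_extreme_work(f1$filtered)
  expect_equal(f2$filtered$records, f1$filtered$records)

  # emptying a direction is an error naming it
  allbig <- make_work_set(c(2000, 3000), c(-1, -2))
  err <- tryCatch(filter_extreme_work(allbig), condition = identity)
  expect_s3_class(err, "abfe_emptiness_error")
  expect_match(conditionMessage(err), "forward")
})

test_that("Bennett MLE solves the crossing point and recovers Gaussian truth", {
  ws <- make_work_set(c(5, 5), c(-5, -5))
  expect_equal(bar_mle(ws, ctx_kT1)$value, 5, tolerance = 1e-8)

  ws_g <- gaussian_work_set(dG = 5, sigma = sqrt(2), n_fwd = 1e4,
                            n_rev = 1e4, n_replicas = 10, ctx = ctx_kT1,
                            seed = 101)
  expect_equal(mean(forward_works(ws_g)), 6, tolerance = 3 * sqrt(2) / 100)
  expect_equal(mean(reverse_works(ws_g)), -4, tolerance = 3 * sqrt(2) / 100)
  est <- bar_mle(ws_g, ctx_kT1)
  expect_lt(abs(est$value - 5), 3 * est$stderr)
  expect_gt(est$stderr, 0)
})

test_that("Bennett MLE is exactly antisymmetric under role exchange", {
  ws <- gaussian_work_set(dG = 3, sigma = 2, n_fwd = 300, n_rev = 200,
                          n_replicas = 1, ctx = ctx_kT1, seed = 55)
  r <- ws$records
  swapped <- work_set(ifelse(r$direction == "forward", "reverse", "forward"),
                      r$replica_id, r$work)
  a <- bar_mle(ws, ctx_kT1)$value
  b <- bar_mle(swapped, ctx_kT1)$value
  expect_equal(b, -a, tolerance = 1e-7)
})

test_that("Bennett MLE reports non-overlapping sets as convergence failures", {
  far <- make_work_set(c(5000, 5001), c(4000, 4001))
  expect_error(bar_mle(far, ctx_kT1), class = "abfe_convergence_error")
})

test_that("Jarzynski matches its closed forms and obeys the Jensen bound", {
  expect_equal(jarzynski(7, ctx_kT1)$value, 7)
  expect_equal(jarzynski(rep(-2.5, 50), ctx_kT1)$value, -2.5)

  # Gaussian works N(6, 2) with kT = 1 -> dG = mu - sigma^2/2 = 5
  set.seed(31)
  w <- rnorm(1e5, 6, sqrt(2))
  expect_equal(jarzynski(w, ctx_kT1)$value, 5, tolerance = 0.05)

  # Jensen: estimate never exceeds the mean work, any input
  for (s in 1:20) {
    set.seed(s)
    w <- switch(1 + s %% 3,
                rnorm(40, s, 3),
                rcauchy(40),
                rexp(40) - s)
    expect_lte(jarzynski(w, ctx_kT1)$value, mean(w) + 1e-10)
  }
})

test_that("pooled NEQ estimate carries between-replica uncertainty", {
  ws <- gaussian_work_set(dG = 5, sigma = sqrt(2), n_fwd = 2000,
                          n_rev = 2000, n_replicas = 10, ctx = ctx_kT1,
                          seed = 77)
  est <- neq_free_energy(ws, ctx_kT1)
  expect_lt(abs(est$value - 5), 3 * est$stderr)
  expect_equal(est$n_replicas, 10)
  expect_length(est$meta$per_replica_dG, 10)
  expect_equal(est$value, bar_mle(ws, ctx_kT1)$value)

  # identical per-replica sets -> zero between-replica spread
  fwd1 <- c(4.8, 5.2, 6.1)
  rev1 <- c(-4.1, -3.9, -5.5)
  ws_id <- work_set(rep(c("forward", "reverse"), each = 9),
                    rep(rep(1:3, each = 3), 2),
                    c(rep(fwd1, 3), rep(rev1, 3)))
  est_id <- neq_free_energy(ws_id, ctx_kT1)
  expect_equal(est_id$stderr, 0)

  # pooled value ignores replica labels
  r <- ws$records
  relabeled <- work_set(r$direction, ((r$replica_id + 2) %% 10) + 1, r$work)
  expect_equal(neq_free_energy(relabeled, ctx_kT1)$value, est$value)

  # replicas with too few works in a direction are refused, listing them
  ws_deg <- work_set(c("forward", "forward", "reverse", "reverse",
                       "forward", "reverse"),
                     c(1L, 1L, 1L, 1L, 2L, 2L), c(1, 2, -1, -2, 1.5, -1.5))
  expect_error(neq_free_energy(ws_deg, ctx_kT1),
               class = "abfe_degenerate_error")
})

test_that("OU-switching accuracy and precision improve with transition length", {
  m <- harmonic_model(1, 4, kT = kT300)
  ctxm <- thermo_context(m$kT / BOLTZMANN_KCAL)
  stats <- sapply(c(25, 100, 400), function(ns) {
    bias <- se <- numeric(10)
    for (s in 1:10) {
      n <- 200
      wf <- ou_switching_work(m, ns, 2, 20, n, "forward",
                              seed = 1000 * s + ns)
      wr <- ou_switching_work(m, ns, 2, 20, n, "reverse",
                              seed = 2000 * s + ns)
      ws <- make_work_set(wf, wr, rep(rep(1:5, each = n / 5)),
                          rep(rep(1:5, each = n / 5)))
      est <- neq_free_energy(ws, ctxm)
      bias[s] <- abs(est$value - m$dG_true)
      se[s] <- est$stderr
    }
    c(bias = mean(bias), se = mean(se))
  })
  expect_true(all(diff(stats["bias", ]) < 0))
  expect_true(all(diff(stats["se", ]) < 0))
})
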