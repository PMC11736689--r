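# Shared test helpers and independent oracles.

kT300 <- abfetools::BOLTZMANN_KCAL * 300

# thermo context with kT exactly 1 kcal/mol, convenient for closed forms
ctx_kT1 <- thermo_context(1 / abfetools::BOLTZMANN_KCAL)

# Independent numerical oracle for the Boresch restraint free energy: the
# full 6-D restrained configurational integral
#   Z = int r^2 sin(thA) sin(thB) exp(-U/kT) dr dthA dthB dphiA dphiB dphiC
# evaluated numerically. The integrand factorizes across the six
# coordinates, so the 6-D integral is the exact product of six 1-D
# quadratures (each via stats::integrate). No stiff-spring approximation is
# made, which is what lets it check the closed form.
boresch_quadrature_oracle <- function(p, kT) {
  z_r <- stats::integrate(function(r) {
    r^2 * exp(-p$Kr * (r - p$r0)^2 / (2 * kT))
  }, 0, Inf, rel.tol = 1e-10)$value
  z_theta <- function(K, th0) {
    stats::integrate(function(th) {
      sin(th) * exp(-K * (th - th0)^2 / (2 * kT))
    }, 0, pi, rel.tol = 1e-10)$value
  }
  z_phi <- function(K) {
    stats::integrate(function(ph) exp(-K * ph^2 / (2 * kT)),
                     -pi, pi, rel.tol = 1e-10)$value
  }
  Z <- z_r * z_theta(p$KthetaA, p$thetaA0) * z_theta(p$KthetaB, p$thetaB0) *
    z_phi(p$KphiA) * z_phi(p$KphiB) * z_phi(p$KphiC)
  -kT * log(8 * pi^2 * p$V0 / Z)
}

# quick constructor for a work set from bare vectors
make_work_set <- function(fwd, rev, reps_f = rep(1L, length(fwd)),
                          reps_r = rep(1L, length(rev))) {
  work_set(c(rep("forward", length(fwd)), rep("reverse", length(rev))),
           c(reps_f, reps_r), c(fwd, rev))
}

# small rectangular gradient ensemble with deterministic samples
make_gradient_ensemble <- function(n_lambda = 3, n_rep = 2, n_samp = 5,
                                   fun = function(lam, r, i) lam * 10 + r + i / 10) {
  sched <- lambda_schedule(seq(0, 1, length.out = n_lambda))
  series <- list()
  for (lam in sched$values) {
    for (r in seq_len(n_rep)) {
      series[[length(series) + 1L]] <- gradient_series(
        replica_id = r, lambda = lam,
        samples = fun(lam, r, seq_len(n_samp)),
        times = 2 * seq_len(n_samp))
    }
  }
  ensemble_gradients("complex_alchemical", sched, series)
}

expect_abfe_error <- function(expr, class) {
  expect_error(expr, class = class)
}
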