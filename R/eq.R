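#' Bootstrapped ensemble mean of ∂H/∂λ at one window
#'
#' Implements the ensemble-averaged bootstrap used by the equilibrium
#' estimator: in each bootstrap iteration every replica's samples are
#' resampled with replacement, the replica mean is taken, and replica means
#' are then averaged across the ensemble. The returned mean is the mean of
#' the bootstrap ensemble means; the standard error is their standard
#' deviation. No block bootstrap is applied (samples are treated as given).
#'
#' Replicas are processed in increasing replica-id order and each draws from
#' its own sub-stream keyed to its *position* in that order, so relabelling
#' replicas does not change the result for a given seed.
#'
#' @param series List of [gradient_series()] at one λ (>= 1 replica, each
#'   with >= 2 samples).
#' @param n_boot Number of bootstrap iterations, >= 100 (default 1000).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return List with `mean` and `stderr` (kcal/mol).
#' @export
bootstrap_lambda_mean <- function(series, n_boot = 1000, seed) {
  abfe_assert(is.list(series) && length(series) >= 1L &&
                all(vapply(series, inherits, TRUE, "gradient_series")),
              "series must be a non-empty list of gradient_series",
              "abfe_domain_error")
  abfe_assert(is_count(n_boot) && n_boot >= 100,
              "n_boot must be an integer >= 100", "abfe_parameter_error")
  abfe_assert(is_count(seed, min = 0L), "seed must be a non-negative integer",
              "abfe_parameter_error")
  short <- vapply(series, function(s) length(s$samples) < 2L, TRUE)
  if (any(short)) {
    abfe_stop(sprintf(
      "replica(s) %s have a single sample; bootstrap is degenerate",
      paste(vapply(series[short], function(s) s$replica_id, 0L),
            collapse = ", ")), "abfe_degenerate_error")
  }
  series <- series[order(vapply(series, function(s) s$replica_id, 0L))]
  R <- length(series)
  boot_rep_means <- matrix(0, nrow = n_boot, ncol = R)
  for (r in seq_len(R)) {
    x <- series[[r]]$samples
    n <- length(x)
    set.seed(derive_seed(seed, r))
    idx <- sample.int(n, n_boot * n, replace = TRUE)
    boot_rep_means[, r] <- rowMeans(matrix(x[idx], nrow = n_boot))
  }
  ens_means <- rowMeans(boot_rep_means)
  list(mean = mean(ens_means), stderr = stats::sd(ens_means))
}

#' Per-λ ensemble-mean profile
#'
#' @param schedule A [lambda_schedule()].
#' @param means Per-λ ensemble-averaged ⟨∂H/∂λ⟩, kcal/mol.
#' @param stderrs Per-λ standard errors, kcal/mol (>= 0).
#' @return An object of class `lambda_mean_profile`.
#' @export
lambda_mean_profile <- function(schedule, means, stderrs) {
  abfe_assert(inherits(schedule, "lambda_schedule"),
              "schedule must be a lambda_schedule", "abfe_domain_error")
  K <- length(schedule$values)
  abfe_assert(is.numeric(means) && length(means) == K,
              "means must match the schedule length", "abfe_format_error")
  abfe_assert(is.numeric(stderrs) && length(stderrs) == K &&
                all(stderrs >= 0),
              "stderrs must match the schedule length and be >= 0",
              "abfe_format_error")
  structure(list(schedule = schedule, means = as.numeric(means),
                 stderrs = as.numeric(stderrs)),
            class = "lambda_mean_profile")
}

#' Thermodynamic integration over a λ-mean profile
#'
#' Computes \eqn{\Delta G = \int_0^1 \langle \partial H/\partial\lambda
#' \rangle \, d\lambda} by trapezoidal quadrature over the (generally
#' unevenly spaced) schedule. The uncertainty propagates the per-window
#' standard errors through the trapezoid weights, treating windows as
#' independent: \eqn{\mathrm{SE}^2 = \sum_k w_k^2 \sigma_k^2} with
#' \eqn{w_1 = (\lambda_2-\lambda_1)/2}, \eqn{w_K =
#' (\lambda_K-\lambda_{K-1})/2} and \eqn{w_k =
#' (\lambda_{k+1}-\lambda_{k-1})/2} otherwise.
#'
#' @param profile A [lambda_mean_profile()].
#' @return A [free_energy_estimate()] with method `"TI"`.
#' @export
ti_integrate <- function(profile) {
  abfe_assert(inherits(profile, "lambda_mean_profile"),
              "profile must be a lambda_mean_profile", "abfe_domain_error")
  abfe_assert(all(is.finite(profile$means)),
              "non-finite lambda means", "abfe_numeric_error")
  w <- trapezoid_weights(profile$schedule$values)
  value <- sum(w * profile$means)
  stderr <- sqrt(sum(w^2 * profile$stderrs^2))
  free_energy_estimate(value, stderr, "TI",
                       meta = list(schedule = profile$schedule$name))
}

trapezoid_weights <- function(lam) {
  K <- length(lam)
  w <- numeric(K)
  w[1] <- (lam[2] - lam[1]) / 2
  w[K] <- (lam[K] - lam[K - 1]) / 2
  if (K > 2) {
    k <- 2:(K - 1)
    w[k] <- (lam[k + 1] - lam[k - 1]) / 2
  }
  w
}

#' Equilibrium (TI) free energy of one leg
#'
#' Applies [bootstrap_lambda_mean()] at every λ-window of a rectangular
#' replica ensemble, then integrates the profile with [ti_integrate()].
#' Deterministic for a fixed seed (window `k` uses a sub-seed keyed to `k`).
#'
#' @param data An [ensemble_gradients()] object.
#' @param n_boot Bootstrap iterations per window (default 1000).
#' @param seed Integer seed.
#' @return A [free_energy_estimate()] with method `"TI"` and `n_replicas`
#'   set to the ensemble size.
#' @examples
#' sched <- builtin_schedule("coupling13")
#' sim <- harmonic_ti_ensemble(harmonic_model(1, 4), sched,
#'                             ensemble_size = 5, n_samples = 50, seed = 1)
#' eq_free_energy(sim$gradients, n_boot = 200, seed = 1)
#' @export
eq_free_energy <- function(data, n_boot = 1000, seed) {
  abfe_assert(inherits(data, "ensemble_gradients"),
              "data must be ensemble_gradients", "abfe_domain_error")
  lam <- data$schedule$values
  means <- numeric(length(lam))
  ses <- numeric(length(lam))
  for (k in seq_along(lam)) {
    bl <- bootstrap_lambda_mean(series_at_lambda(data, lam[k]),
                                n_boot = n_boot,
                                seed = derive_seed(seed, 104729L, k))
    means[k] <- bl$mean
    ses[k] <- bl$stderr
  }
  est <- ti_integrate(lambda_mean_profile(data$schedule, means, ses))
  est$n_replicas <- length(data$replica_ids)
  est$meta <- list(leg = data$leg, schedule = data$schedule$name,
                   n_boot = n_boot, seed = seed)
  est
}

#' Running average over an ordered replica ensemble
#'
#' Element `k` is the mean of the first `k` per-replica ΔG values; used to
#' judge convergence of the prediction with growing ensemble size.
#'
#' @param per_replica_dG Ordered numeric vector of per-replica ΔG values,
#'   kcal/mol.
#' @return Numeric vector of cumulative means, same length as the input.
#' @export
running_average_by_ensemble_size <- function(per_replica_dG) {
  abfe_assert(is.numeric(per_replica_dG) && length(per_replica_dG) >= 1L &&
                all(is.finite(per_replica_dG)),
              "per_replica_dG must be a non-empty finite numeric vector",
              "abfe_domain_error")
  cumsum(per_replica_dG) / seq_along(per_replica_dG)
}
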