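#' Analytically solvable harmonic alchemical system
#'
#' A one-dimensional particle in a harmonic well whose stiffness is
#' interpolated linearly along the alchemical path,
#' \eqn{k(\lambda) = (1-\lambda) k_0 + \lambda k_1}, so
#' \eqn{H(\lambda, x) = k(\lambda) x^2 / 2} and
#' \eqn{\partial H/\partial\lambda = (k_1 - k_0) x^2 / 2}. Every estimator
#' in the package has a closed form on this system; in particular
#' \eqn{\Delta G_{true} = (kT/2) \ln(k_1/k_0)}.
#'
#' @param k0,k1 End-state spring constants, kcal/mol/Å² (> 0).
#' @param kT Thermal energy, kcal/mol (default that of 300 K).
#' @return An object of class `harmonic_model` with `k0`, `k1`, `kT`, and
#'   `dG_true`.
#' @export
harmonic_model <- function(k0, k1, kT = thermo_context()$kT) {
  abfe_assert(is_number(k0) && k0 > 0 && is_number(k1) && k1 > 0,
              "spring constants must be positive", "abfe_domain_error")
  abfe_assert(is_number(kT) && kT > 0, "kT must be positive",
              "abfe_domain_error")
  structure(list(k0 = k0, k1 = k1, kT = kT,
                 dG_true = kT / 2 * log(k1 / k0)),
            class = "harmonic_model")
}

harmonic_k <- function(m, lambda) (1 - lambda) * m$k0 + lambda * m$k1

#' Replica-resolved TI ensemble from the harmonic system
#'
#' At each λ-window and replica, draws `n_samples` equilibrium positions
#' \eqn{x \sim N(0, kT/k(\lambda))} independently and emits the gradient
#' samples \eqn{(k_1-k_0) x^2/2}. The analytic per-window mean is
#' \eqn{(k_1-k_0) \, kT / (2 k(\lambda))}. Each (window, replica) cell uses
#' its own deterministic sub-stream of `seed`.
#'
#' @param m A [harmonic_model()].
#' @param schedule A [lambda_schedule()].
#' @param ensemble_size Number of replicas.
#' @param n_samples Samples per window per replica.
#' @param seed Integer seed.
#' @return List with `gradients` (an [ensemble_gradients()], leg
#'   `complex_alchemical`) and `dG_true` (kcal/mol).
#' @export
harmonic_ti_ensemble <- function(m, schedule, ensemble_size, n_samples,
                                 seed) {
  abfe_assert(inherits(m, "harmonic_model"), "m must be a harmonic_model",
              "abfe_domain_error")
  abfe_assert(inherits(schedule, "lambda_schedule"),
              "schedule must be a lambda_schedule", "abfe_domain_error")
  abfe_assert(is_count(ensemble_size) && is_count(n_samples),
              "ensemble_size and n_samples must be integers >= 1",
              "abfe_parameter_error")
  abfe_assert(is_count(seed, min = 0L), "seed must be a non-negative integer",
              "abfe_parameter_error")
  dk <- m$k1 - m$k0
  series <- list()
  for (k in seq_along(schedule$values)) {
    klam <- harmonic_k(m, schedule$values[k])
    for (r in seq_len(ensemble_size)) {
      set.seed(derive_seed(seed, k, r))
      x <- stats::rnorm(n_samples, mean = 0, sd = sqrt(m$kT / klam))
      series[[length(series) + 1L]] <-
        gradient_series(replica_id = r, lambda = schedule$values[k],
                        samples = dk * x^2 / 2)
    }
  }
  list(gradients = ensemble_gradients("complex_alchemical", schedule,
                                      series),
       dG_true = m$dG_true)
}

#' Crooks-consistent Gaussian work sets
#'
#' Draws forward works from \eqn{N(\Delta G + \sigma^2/2kT, \sigma^2)} and
#' reverse works from \eqn{N(-\Delta G + \sigma^2/2kT, \sigma^2)}; this
#' pair satisfies the Crooks fluctuation theorem exactly in distribution
#' (each direction dissipates \eqn{\sigma^2/2kT} on average). Records are
#' tagged evenly across replicas in both directions.
#'
#' @param dG Ground-truth free energy, kcal/mol.
#' @param sigma Work standard deviation, kcal/mol (> 0).
#' @param n_fwd,n_rev Work counts per direction; each divisible by
#'   `n_replicas`.
#' @param n_replicas Number of end-state replicas the records are tagged
#'   with.
#' @param ctx A [thermo_context()].
#' @param seed Integer seed.
#' @return A [work_set()].
#' @export
gaussian_work_set <- function(dG, sigma, n_fwd, n_rev, n_replicas = 1L,
                              ctx = thermo_context(), seed) {
  abfe_assert(is_number(dG), "dG must be a finite number",
              "abfe_domain_error")
  abfe_assert(is_number(sigma) && sigma > 0, "sigma must be > 0",
              "abfe_parameter_error")
  abfe_assert(is_count(n_fwd) && is_count(n_rev) && is_count(n_replicas),
              "counts must be integers >= 1", "abfe_parameter_error")
  if (n_fwd %% n_replicas != 0 || n_rev %% n_replicas != 0) {
    abfe_stop("n_fwd and n_rev must be divisible by n_replicas",
              "abfe_parameter_error")
  }
  abfe_assert(is_count(seed, min = 0L), "seed must be a non-negative integer",
              "abfe_parameter_error")
  diss <- sigma^2 / (2 * ctx$kT)
  set.seed(derive_seed(seed, 11L))
  w_f <- stats::rnorm(n_fwd, mean = dG + diss, sd = sigma)
  set.seed(derive_seed(seed, 12L))
  w_r <- stats::rnorm(n_rev, mean = -dG + diss, sd = sigma)
  work_set(direction = c(rep("forward", n_fwd), rep("reverse", n_rev)),
           replica_id = c(rep(seq_len(n_replicas), each = n_fwd / n_replicas),
                          rep(seq_len(n_replicas), each = n_rev / n_replicas)),
           work = c(w_f, w_r))
}

#' Nonequilibrium switching works from Ornstein-Uhlenbeck dynamics
#'
#' Emulates fast alchemical transitions on the harmonic system: each
#' transition starts from an exact equilibrium draw of its initial
#' end-state and propagates the coordinate by overdamped
#' Ornstein-Uhlenbeck dynamics in the instantaneous potential while λ is
#' switched linearly over `n_steps` increments. Work accumulates as
#' \eqn{W = \sum_i [H(\lambda_{i+1}, x_i) - H(\lambda_i, x_i)]}. The OU
#' friction is identical in both directions (a property of the medium, as
#' the Crooks theorem requires); `relax_time` is the coordinate relaxation
#' time at the λ = 0 stiffness; slower switching (larger
#' `n_steps * dt` at fixed `relax_time`) dissipates less, approaching
#' \eqn{\langle W \rangle \to \Delta G_{true}} in the quasi-static limit,
#' while a single-step switch reproduces the free-energy-perturbation
#' identity.
#'
#' @param m A [harmonic_model()].
#' @param n_steps Number of λ increments per transition; `n_steps = 1` is
#'   the instantaneous-switch (free-energy-perturbation) limit.
#' @param dt Time step, ps (> 0).
#' @param relax_time Relaxation time at the initial state, ps (> 0).
#' @param n_transitions Number of transitions.
#' @param direction `"forward"` (λ 0→1) or `"reverse"` (1→0).
#' @param seed Integer seed.
#' @return Numeric vector of `n_transitions` works, kcal/mol.
#' @export
ou_switching_work <- function(m, n_steps, dt, relax_time, n_transitions,
                              direction = c("forward", "reverse"), seed) {
  abfe_assert(inherits(m, "harmonic_model"), "m must be a harmonic_model",
              "abfe_domain_error")
  direction <- match.arg(direction)
  abfe_assert(is_count(n_steps), "n_steps must be an integer >= 1",
              "abfe_parameter_error")
  abfe_assert(is_number(dt) && dt > 0 && is_number(relax_time) &&
                relax_time > 0,
              "dt and relax_time must be > 0", "abfe_parameter_error")
  abfe_assert(is_count(n_transitions), "n_transitions must be >= 1",
              "abfe_parameter_error")
  abfe_assert(is_count(seed, min = 0L), "seed must be a non-negative integer",
              "abfe_parameter_error")

  lam <- seq(0, 1, length.out = n_steps + 1L)
  if (direction == "reverse") lam <- rev(lam)
  k_init <- harmonic_k(m, lam[1])
  # friction is a property of the medium, identical in both directions
  # (required for the Crooks theorem); relax_time is the relaxation time at
  # the lambda = 0 stiffness, so at stiffness k it is relax_time * k0 / k
  gamma <- relax_time * m$k0

  set.seed(derive_seed(seed, if (direction == "forward") 21L else 22L))
  # all transitions propagated in parallel as a vector
  x <- stats::rnorm(n_transitions, 0, sqrt(m$kT / k_init))
  W <- numeric(n_transitions)
  for (i in seq_len(n_steps)) {
    k_old <- harmonic_k(m, lam[i])
    k_new <- harmonic_k(m, lam[i + 1L])
    W <- W + (k_new - k_old) * x^2 / 2
    # exact OU update over dt at fixed stiffness k_new
    decay <- exp(-k_new * dt / gamma)
    sd_eq <- sqrt(m$kT / k_new * (1 - decay^2))
    x <- x * decay + stats::rnorm(n_transitions, 0, sd_eq)
  }
  W
}

#' Contaminate a work set with extreme forward values
#'
#' Appends `count` forward records whose work is at or above `magnitude`
#' (must exceed the 1000 kcal/mol filter cutoff so that
#' [filter_extreme_work()] removes exactly these), with random replica
#' tags drawn from the existing forward replicas. Emulates the occasional
#' extreme forward work values of coupling transitions in the protein
#' environment.
#'
#' @param ws A [work_set()].
#' @param count Number of extreme records to append (<= number of forward
#'   records).
#' @param magnitude Minimum extreme work, kcal/mol (>= 1001).
#' @param seed Integer seed.
#' @return The contaminated [work_set()].
#' @export
inject_extremes <- function(ws, count, magnitude = 1500, seed) {
  abfe_assert(inherits(ws, "work_set"), "ws must be a work_set",
              "abfe_domain_error")
  abfe_assert(is_count(count, min = 0L), "count must be an integer >= 0",
              "abfe_parameter_error")
  n_fwd <- ws$meta$n_fwd
  abfe_assert(count <= n_fwd, "count must not exceed the forward records",
              "abfe_parameter_error")
  if (!(is_number(magnitude) && magnitude > 1000)) {
    abfe_stop("magnitude must exceed 1000 kcal/mol or the extremes would survive the filter",
              "abfe_parameter_error")
  }
  if (count == 0L) return(ws)
  set.seed(derive_seed(seed, 31L))
  reps <- unique(ws$records$replica_id[ws$records$direction == "forward"])
  r <- ws$records
  extra <- data.frame(
    direction = rep("forward", count),
    replica_id = sample(reps, count, replace = TRUE),
    work = magnitude + stats::runif(count, 0, 100),
    stringsAsFactors = FALSE)
  out <- rbind(r, extra)
  work_set(out$direction, out$replica_id, out$work,
           ws$transition_length_fwd, ws$transition_length_rev)
}

#' Skew-normal ensembles of per-replica ΔG values
#'
#' Draws from the skew-normal distribution
#' \eqn{x = \mu + s(\delta |u_0| + \sqrt{1-\delta^2} u_1)} with
#' \eqn{\delta = \alpha/\sqrt{1+\alpha^2}} and independent standard
#' normals \eqn{u_0, u_1}; mimics the skewed, fat-tailed per-replica ΔG
#' distributions seen in large ensembles. The analytic skewness implied by
#' `alpha` is returned for verification.
#'
#' @param mu Location, kcal/mol.
#' @param scale Scale, kcal/mol (> 0).
#' @param alpha Skew parameter (0 = Gaussian).
#' @param n Number of draws (>= 4).
#' @param seed Integer seed.
#' @return Numeric vector of `n` values with attribute
#'   `analytic_skewness`.
#' @export
skewed_dg_ensemble <- function(mu, scale, alpha, n, seed) {
  abfe_assert(is_number(mu) && is_number(alpha), "mu, alpha must be finite",
              "abfe_domain_error")
  abfe_assert(is_number(scale) && scale > 0, "scale must be > 0",
              "abfe_parameter_error")
  abfe_assert(is_count(n, min = 4L), "n must be an integer >= 4",
              "abfe_parameter_error")
  abfe_assert(is_count(seed, min = 0L), "seed must be a non-negative integer",
              "abfe_parameter_error")
  delta <- alpha / sqrt(1 + alpha^2)
  set.seed(derive_seed(seed, 41L))
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  x <- mu + scale * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
  b <- delta * sqrt(2 / pi)
  skew <- (4 - pi) / 2 * b^3 / (1 - b^2)^1.5
  structure(x, analytic_skewness = skew)
}
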