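#' Work of one nonequilibrium transition
#'
#' Integrates ∂H/∂λ over the course of a fast switching transition:
#' \eqn{W = \int \partial H/\partial\lambda \; d\lambda} by trapezoidal
#' quadrature along the λ(t) path. The sign follows the path direction, so
#' a reverse (1→0) transition over the same gradient gives the negated
#' work.
#'
#' @param series A [gradient_series()] with `times` present, sampled along
#'   the transition.
#' @param lambda_path Numeric vector of λ values, one per sample, monotone
#'   from 0 to 1 (forward) or 1 to 0 (reverse).
#' @return Work in kcal/mol.
#' @export
integrate_work <- function(series, lambda_path) {
  abfe_assert(inherits(series, "gradient_series"),
              "series must be a gradient_series", "abfe_domain_error")
  abfe_assert(!is.null(series$times),
              "series must carry sample times for work integration",
              "abfe_format_error")
  abfe_assert(is.numeric(lambda_path) &&
                length(lambda_path) == length(series$samples),
              "lambda_path length must match the number of samples",
              "abfe_format_error")
  d <- diff(lambda_path)
  if (!(all(d >= 0) || all(d <= 0)) || all(d == 0)) {
    abfe_stop("lambda_path must be monotone (0 to 1 or 1 to 0)",
              "abfe_domain_error")
  }
  g <- series$samples
  n <- length(g)
  sum((g[-1] + g[-n]) / 2 * d)
}

# Bennett/Crooks maximum-likelihood self-consistency residual; its unique
# root in dG is the MLE. fwd are works of 0->1 transitions, rev of 1->0.
bar_residual <- function(dG, fwd, rev, kT) {
  n_f <- length(fwd)
  n_r <- length(rev)
  lhs <- sum(stats::plogis(-((fwd - dG) / kT + log(n_f / n_r))))
  rhs <- sum(stats::plogis(-((rev + dG) / kT + log(n_r / n_f))))
  lhs - rhs
}

#' Bidirectional maximum-likelihood (Crooks/Bennett) estimate
#'
#' Solves the Bennett self-consistency equation
#' \deqn{\sum_i \left[1 + \tfrac{n_f}{n_r} e^{(W_{f,i} - \Delta G)/kT}
#'   \right]^{-1} = \sum_j \left[1 + \tfrac{n_r}{n_f} e^{(W_{r,j} +
#'   \Delta G)/kT}\right]^{-1}}
#' for ΔG by bracketed root finding (tolerance 1e-8 kcal/mol, bracket
#' ±1e4 kcal/mol). This is the maximum-likelihood estimator implied by the
#' Crooks fluctuation theorem: forward works \eqn{W_f} come from 0→1
#' transitions, reverse works \eqn{W_r} from 1→0 transitions (stored with
#' their own sign, i.e. the Crooks pairing compares \eqn{W_f} with
#' \eqn{-W_r}).
#'
#' The standard error is the asymptotic maximum-likelihood (Fisher
#' information) estimate
#' \eqn{\mathrm{Var}(\Delta G)/ (kT)^2 = \left[\sum f(1-f)\right]^{-1} -
#' (1/n_f + 1/n_r)} with logistic \eqn{f} evaluated at the solution; it
#' reflects within-set sampling noise only (for between-replica errors see
#' [neq_free_energy()]).
#'
#' @param ws A [work_set()] (already filtered, see
#'   [filter_extreme_work()]) with >= 2 works in each direction.
#' @param ctx A [thermo_context()].
#' @return A [free_energy_estimate()] with method `"BAR_MLE"`.
#' @examples
#' ctx <- thermo_context()
#' ws <- gaussian_work_set(dG = -8, sigma = 1.5, n_fwd = 500, n_rev = 500,
#'                         n_replicas = 5, ctx = ctx, seed = 7)
#' bar_mle(ws, ctx)
#' @export
bar_mle <- function(ws, ctx = thermo_context()) {
  abfe_assert(inherits(ws, "work_set"), "ws must be a work_set",
              "abfe_domain_error")
  abfe_assert(inherits(ctx, "thermo_context"),
              "ctx must be a thermo_context", "abfe_domain_error")
  fwd <- forward_works(ws)
  rev <- reverse_works(ws)
  abfe_assert(length(fwd) >= 2 && length(rev) >= 2,
              "need >= 2 work values in each direction",
              "abfe_domain_error")
  kT <- ctx$kT
  lo <- -1e4
  hi <- 1e4
  f_lo <- bar_residual(lo, fwd, rev, kT)
  f_hi <- bar_residual(hi, fwd, rev, kT)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0) {
    abfe_stop(paste0(
      "no bracketing root for the Bennett equation in [-1e4, 1e4] kcal/mol;",
      " check the overlap between forward and reverse work distributions"),
      "abfe_convergence_error")
  }
  root <- stats::uniroot(bar_residual, c(lo, hi), fwd = fwd, rev = rev,
                         kT = kT, tol = 1e-8)$root

  # asymptotic MLE variance at the solution
  n_f <- length(fwd)
  n_r <- length(rev)
  M <- log(n_f / n_r)
  x <- c((fwd - root) / kT + M, (rev + root) / kT - M)
  p <- stats::plogis(-abs(x))
  info <- sum(p * (1 - p))
  if (info <= 0 || !is.finite(info)) {
    abfe_stop(paste0(
      "the Fisher information at the Bennett solution vanishes ",
      "(no effective overlap between forward and reverse work ",
      "distributions); the estimate is unreliable"),
      "abfe_convergence_error")
  }
  var_beta <- max(1 / info - (1 / n_f + 1 / n_r), 0)
  free_energy_estimate(root, kT * sqrt(var_beta), "BAR_MLE",
                       meta = list(n_fwd = n_f, n_rev = n_r))
}

#' Jarzynski (unidirectional exponential-average) estimate
#'
#' \deqn{\Delta G = -kT \ln \langle e^{-W/kT} \rangle}
#' computed with log-sum-exp stabilization. Forward works estimate +ΔG of
#' the forward process. The estimator is biased at finite sample size and
#' never exceeds the mean work (Jensen's inequality); it is highly
#' sensitive to rare low-work tails. The standard error is a delta-method
#' propagation of the exponential average.
#'
#' @param works Numeric vector of works from one direction, kcal/mol.
#' @param ctx A [thermo_context()].
#' @return A [free_energy_estimate()] with method `"JARZYNSKI"`.
#' @export
jarzynski <- function(works, ctx = thermo_context()) {
  abfe_assert(is.numeric(works) && length(works) >= 1L &&
                all(is.finite(works)),
              "works must be a non-empty finite numeric vector",
              "abfe_domain_error")
  abfe_assert(inherits(ctx, "thermo_context"),
              "ctx must be a thermo_context", "abfe_domain_error")
  kT <- ctx$kT
  lme <- logmeanexp(-works / kT)
  value <- -kT * lme$logmean
  n <- length(works)
  w <- lme$weights
  stderr <- if (n > 1) kT * stats::sd(w) / (mean(w) * sqrt(n)) else 0
  free_energy_estimate(value, stderr, "JARZYNSKI", meta = list(n = n))
}

#' Nonequilibrium free energy with between-replica uncertainty
#'
#' The reported value is [bar_mle()] over all pooled works (both
#' directions, all replicas). The uncertainty is obtained by adapting the
#' ensemble approach to the nonequilibrium setting: a separate bidirectional
#' estimate is computed per equilibrium replica (using only the works whose
#' transitions started from that replica at each end-state), and the
#' standard error across these per-replica ΔG values (sample SD / sqrt(R))
#' is reported.
#'
#' @param ws A filtered [work_set()] whose replica-id sets are equal across
#'   directions.
#' @param ctx A [thermo_context()].
#' @return A [free_energy_estimate()] with method `"BAR_MLE"`,
#'   `n_replicas = R`, and the per-replica estimates in
#'   `meta$per_replica_dG`.
#' @export
neq_free_energy <- function(ws, ctx = thermo_context()) {
  abfe_assert(inherits(ws, "work_set"), "ws must be a work_set",
              "abfe_domain_error")
  r <- ws$records
  reps_f <- sort(unique(r$replica_id[r$direction == "forward"]))
  reps_r <- sort(unique(r$replica_id[r$direction == "reverse"]))
  abfe_assert(length(reps_f) > 0 && length(reps_r) > 0,
              "both directions must be present", "abfe_domain_error")
  abfe_assert(identical(reps_f, reps_r),
              "replica-id sets differ between directions; per-replica UQ needs matched ids",
              "abfe_domain_error")
  degen <- Filter(function(id) {
    sum(r$direction == "forward" & r$replica_id == id) < 2 ||
      sum(r$direction == "reverse" & r$replica_id == id) < 2
  }, reps_f)
  if (length(degen) > 0) {
    abfe_stop(sprintf(
      "replica(s) %s have < 2 works in a direction; per-replica estimates are degenerate",
      paste(unlist(degen), collapse = ", ")), "abfe_degenerate_error")
  }

  pooled <- bar_mle(ws, ctx)
  per_rep <- vapply(reps_f, function(id) {
    sub <- r[r$replica_id == id, , drop = FALSE]
    sub_ws <- work_set(sub$direction, sub$replica_id, sub$work,
                       ws$transition_length_fwd, ws$transition_length_rev)
    bar_mle(sub_ws, ctx)$value
  }, 0)
  R <- length(reps_f)
  stderr <- if (R > 1) stats::sd(per_rep) / sqrt(R) else 0
  free_energy_estimate(pooled$value, stderr, "BAR_MLE", n_replicas = R,
                       meta = list(per_replica_dG = per_rep,
                                   uq = "between-replica SE of per-replica bidirectional MLEs"))
}
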