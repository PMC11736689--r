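#' Overlap coefficient of forward and reverse work distributions
#'
#' Nonzero overlap between the forward and (negated) reverse work
#' distributions is a necessary condition for reliable bidirectional
#' nonequilibrium estimates. The coefficient is the area of intersection of
#' the two normalized distributions: 0 means no overlap, 1 identical
#' distributions.
#'
#' Both samples are histogrammed on shared bins spanning the pooled range
#' (Freedman-Diaconis width on the pooled data, minimum 10 bins); densities
#' are normalized to unit area and the coefficient is
#' \eqn{\sum_b \min(p_{f,b}, p_{r,b}) \Delta_b}, clipped to \[0, 1\]. If
#' all pooled values coincide the distributions are identical point masses
#' and 1 is returned with a degeneracy flag.
#'
#' @param ws A [work_set()] with >= 2 works in each direction (after
#'   filtering).
#' @return Numeric overlap in \[0, 1\], with attributes `n_bins` and
#'   `degenerate`.
#' @export
overlap_coefficient <- function(ws) {
  abfe_assert(inherits(ws, "work_set"), "ws must be a work_set",
              "abfe_domain_error")
  fwd <- forward_works(ws)
  nrv <- -reverse_works(ws)
  abfe_assert(length(fwd) >= 2 && length(nrv) >= 2,
              "need >= 2 works in each direction", "abfe_domain_error")
  pooled <- c(fwd, nrv)
  rng <- range(pooled)
  if (diff(rng) == 0) {
    return(structure(1.0, n_bins = 1L, degenerate = TRUE))
  }
  h <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
  n_bins <- if (h > 0) max(10L, ceiling(diff(rng) / h)) else 10L
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  delta <- diff(breaks)
  count_f <- bin_counts(fwd, breaks)
  count_r <- bin_counts(nrv, breaks)
  p_f <- count_f / (length(fwd) * delta)
  p_r <- count_r / (length(nrv) * delta)
  ovl <- sum(pmin(p_f, p_r) * delta)
  structure(min(max(ovl, 0), 1), n_bins = as.integer(n_bins),
            degenerate = FALSE)
}

# closed on the right, first bin closed on both ends; values guaranteed
# inside [breaks[1], breaks[last]]
bin_counts <- function(x, breaks) {
  idx <- findInterval(x, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tabulate(idx, nbins = length(breaks) - 1L)
}

#' Distance between the inner extremes of the work distributions
#'
#' The difference between the smallest forward work (the distribution
#' toward the right) and the largest negated reverse work (the distribution
#' toward the left): `min(W_f) - max(-W_r)`. Positive values measure the
#' gap between non-overlapping distributions; negative values mean the
#' ranges interleave. Outliers can produce negative distances even at zero
#' overlap.
#'
#' @param ws A [work_set()] with >= 1 work in each direction.
#' @return Distance in kcal/mol.
#' @export
work_distance <- function(ws) {
  abfe_assert(inherits(ws, "work_set"), "ws must be a work_set",
              "abfe_domain_error")
  fwd <- forward_works(ws)
  nrv <- -reverse_works(ws)
  abfe_assert(length(fwd) >= 1 && length(nrv) >= 1,
              "need >= 1 work in each direction", "abfe_domain_error")
  min(fwd) - max(nrv)
}

#' Skewness and excess kurtosis of a sample
#'
#' Population (biased) central-moment estimators:
#' skewness \eqn{m_3/m_2^{3/2}} and excess kurtosis \eqn{m_4/m_2^2 - 3}.
#' Distributions of per-replica ΔG values from ensemble simulations are
#' frequently non-Gaussian (fat tails, skew), which these moments
#' summarize. A sample-adjusted (unbiased-style) variant is available via
#' `adjusted = TRUE`.
#'
#' @param values Numeric vector (>= 4 values, nonzero variance), e.g.
#'   per-replica ΔG or work values.
#' @param adjusted If `TRUE`, apply the standard small-sample adjustment
#'   factors. Default `FALSE` (population form).
#' @return List with `skewness` and `excess_kurtosis`.
#' @export
moment_diagnostics <- function(values, adjusted = FALSE) {
  abfe_assert(is.numeric(values) && length(values) >= 4L &&
                all(is.finite(values)),
              "need >= 4 finite values", "abfe_domain_error")
  n <- length(values)
  x <- values - mean(values)
  m2 <- mean(x^2)
  abfe_assert(m2 > 0, "zero variance: moments are degenerate",
              "abfe_degenerate_error")
  m3 <- mean(x^3)
  m4 <- mean(x^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  if (adjusted) {
    g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
    g2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  list(skewness = g1, excess_kurtosis = g2)
}

#' Full diagnostics report for a work set
#'
#' Bundles [overlap_coefficient()], [work_distance()] and
#' [moment_diagnostics()] (of the pooled works on a common axis) into one
#' report.
#'
#' @param ws A [work_set()].
#' @return An object of class `diagnostics_report` with fields
#'   `overlap_coefficient`, `distance`, `skewness`, `excess_kurtosis`,
#'   `n_fwd`, `n_rev`.
#' @export
work_diagnostics <- function(ws) {
  ovl <- overlap_coefficient(ws)
  pooled <- c(forward_works(ws), -reverse_works(ws))
  mom <- if (length(pooled) >= 4 && stats::var(pooled) > 0) {
    moment_diagnostics(pooled)
  } else {
    list(skewness = NA_real_, excess_kurtosis = NA_real_)
  }
  structure(list(overlap_coefficient = as.numeric(ovl),
                 distance = work_distance(ws),
                 skewness = mom$skewness,
                 excess_kurtosis = mom$excess_kurtosis,
                 n_fwd = ws$meta$n_fwd, n_rev = ws$meta$n_rev,
                 n_bins = attr(ovl, "n_bins"),
                 degenerate = attr(ovl, "degenerate")),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf(
    "<diagnostics_report> overlap %.3f, distance %.3f kcal/mol, skew %.3f, ex.kurt %.3f (%d fwd / %d rev)\n",
    x$overlap_coefficient, x$distance, x$skewness, x$excess_kurtosis,
    x$n_fwd, x$n_rev))
  invisible(x)
}

#' Reliability flags for an estimate
#'
#' The two criteria of reliability used by the recommended protocols: the
#' ensemble standard error must not exceed `se_threshold` (default 0.5
#' kcal/mol), and — for nonequilibrium estimates with diagnostics — the
#' distance between work distributions must not exceed
#' `distance_threshold` (default 0). Thresholds are inclusive (`<=`).
#'
#' @param est A [free_energy_estimate()].
#' @param diag Optional `diagnostics_report` (absent for equilibrium
#'   estimates).
#' @param se_threshold Standard-error threshold, kcal/mol.
#' @param distance_threshold Distance threshold, kcal/mol.
#' @return List with `precision_ok` and `overlap_ok` (`NA` when no
#'   diagnostics are supplied).
#' @export
reliability_flags <- function(est, diag = NULL, se_threshold = 0.5,
                              distance_threshold = 0) {
  abfe_assert(inherits(est, "free_energy_estimate"),
              "est must be a free_energy_estimate", "abfe_domain_error")
  abfe_assert(is_number(se_threshold) && is_number(distance_threshold),
              "thresholds must be finite", "abfe_parameter_error")
  list(
    precision_ok = est$stderr <= se_threshold,
    overlap_ok = if (is.null(diag)) NA else
      diag$distance <= distance_threshold
  )
}
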