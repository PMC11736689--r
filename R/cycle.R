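#' Boresch restraint parameters
#'
#' Parameters of the one-distance, two-angle, three-dihedral restraint set
#' that holds a decoupled ligand in the binding site. Harmonic potentials
#' \eqn{U = (K/2)(x - x_0)^2} are assumed; `V0` is the standard-state
#' volume (1660 Å³, i.e. 1 M).
#'
#' @param r0 Reference distance, Å (> 0).
#' @param thetaA0,thetaB0 Reference angles, radians, in (0, π).
#' @param Kr Distance force constant, kcal/mol/Å².
#' @param KthetaA,KthetaB,KphiA,KphiB,KphiC Angle and dihedral force
#'   constants, kcal/mol/rad².
#' @param V0 Standard-state volume, Å³ (default 1660).
#' @return An object of class `boresch_params`.
#' @export
boresch_params <- function(r0, thetaA0, thetaB0, Kr, KthetaA, KthetaB,
                           KphiA, KphiB, KphiC, V0 = 1660) {
  ks <- c(Kr = Kr, KthetaA = KthetaA, KthetaB = KthetaB, KphiA = KphiA,
          KphiB = KphiB, KphiC = KphiC)
  abfe_assert(all(vapply(ks, is_number, TRUE)) && all(ks > 0),
              "all force constants must be positive numbers",
              "abfe_domain_error")
  abfe_assert(is_number(r0) && r0 > 0, "r0 must be > 0", "abfe_domain_error")
  for (th in c(thetaA0, thetaB0)) {
    abfe_assert(is_number(th) && th > 0 && th < pi,
                "reference angles must lie in (0, pi)", "abfe_domain_error")
  }
  abfe_assert(is_number(V0) && V0 > 0, "V0 must be > 0", "abfe_domain_error")
  structure(list(r0 = r0, thetaA0 = thetaA0, thetaB0 = thetaB0,
                 Kr = Kr, KthetaA = KthetaA, KthetaB = KthetaB,
                 KphiA = KphiA, KphiB = KphiB, KphiC = KphiC, V0 = V0),
            class = "boresch_params")
}

#' Analytic free energy of imposing Boresch restraints
#'
#' Stiff-spring closed form for the free energy of restraining a decoupled
#' ligand at standard-state concentration:
#' \deqn{\Delta G_{restr}^{lig} = -kT \ln\!\left[
#'   \frac{8\pi^2 V_0}{r_0^2 \sin\theta_{A0} \sin\theta_{B0}}
#'   \frac{\sqrt{K_r K_{\theta A} K_{\theta B} K_{\phi A} K_{\phi B}
#'   K_{\phi C}}}{(2\pi kT)^3} \right]}
#' This is the term added in the double-decoupling cycle when the decoupled
#' ligand is restrained within the binding pocket; the standard error is 0
#' (analytic).
#'
#' @param p A [boresch_params()].
#' @param ctx A [thermo_context()].
#' @return A [free_energy_estimate()] with method `"ANALYTIC"`.
#' @examples
#' p <- boresch_params(5, pi / 2, pi / 2, 10, 10, 10, 10, 10, 10)
#' boresch_restraint_dg(p, thermo_context())
#' @export
boresch_restraint_dg <- function(p, ctx = thermo_context()) {
  abfe_assert(inherits(p, "boresch_params"), "p must be boresch_params",
              "abfe_domain_error")
  abfe_assert(inherits(ctx, "thermo_context"),
              "ctx must be a thermo_context", "abfe_domain_error")
  sA <- sin(p$thetaA0)
  sB <- sin(p$thetaB0)
  abfe_assert(sA > 0 && sB > 0, "sin(theta) must be positive",
              "abfe_domain_error")
  kT <- ctx$kT
  prodK <- p$Kr * p$KthetaA * p$KthetaB * p$KphiA * p$KphiB * p$KphiC
  arg <- 8 * pi^2 * p$V0 / (p$r0^2 * sA * sB) *
    sqrt(prodK) / (2 * pi * kT)^3
  free_energy_estimate(-kT * log(arg), 0, "ANALYTIC",
                       meta = list(term = "boresch_restraint",
                                   V0 = p$V0))
}

#' Assemble the double-decoupling cycle
#'
#' The binding free energy from the five cycle terms:
#' \deqn{\Delta G_b = \Delta G_{alch}^{com} - \Delta G_{restr}^{com}
#'   - \Delta G_{alch}^{lig} + \Delta G_{restr}^{lig}
#'   + \Delta G_{conf}^{prot}}
#' The standard error is the square root of the summed component
#' variances (components treated as independent).
#'
#' @param components A [cycle_components()] object.
#' @return A [free_energy_estimate()] with method `"SUM"`.
#' @export
assemble_cycle <- function(components) {
  abfe_assert(inherits(components, "cycle_components"),
              "components must be cycle_components", "abfe_domain_error")
  signs <- c(dG_alch_com = 1, dG_restr_com = -1, dG_alch_lig = -1,
             dG_restr_lig = 1, dG_conf_prot = 1)
  value <- sum(vapply(names(signs),
                      function(nm) signs[[nm]] * components[[nm]]$value, 0))
  stderr <- sqrt(sum(vapply(names(signs),
                            function(nm) components[[nm]]$stderr^2, 0)))
  n_rep <- max(vapply(names(signs),
                      function(nm) components[[nm]]$n_replicas, 0L))
  free_energy_estimate(value, stderr, "SUM", n_replicas = n_rep,
                       meta = list(adjusted = components$adjusted,
                                   convention = paste(
                                     "dG_b = dG_alch_com - dG_restr_com",
                                     "- dG_alch_lig + dG_restr_lig",
                                     "+ dG_conf_prot")))
}

#' Benchmark table of predicted vs experimental binding free energies
#'
#' @param complex_id Character vector of unique complex identifiers.
#' @param system_id Character vector of protein-system labels.
#' @param dG_pred Predicted ΔG, kcal/mol.
#' @param dG_pred_err Standard error of the prediction, kcal/mol (>= 0).
#' @param dG_exp Experimental ΔG, kcal/mol.
#' @return A data frame of class `benchmark_table`.
#' @export
benchmark_table <- function(complex_id, system_id, dG_pred, dG_pred_err,
                            dG_exp) {
  abfe_assert(!anyDuplicated(complex_id), "complex_id must be unique",
              "abfe_format_error")
  abfe_assert(all(nzchar(system_id)), "every row needs a system_id",
              "abfe_format_error")
  abfe_assert(is.numeric(dG_pred_err) && all(dG_pred_err >= 0),
              "dG_pred_err must be >= 0", "abfe_domain_error")
  df <- data.frame(complex_id = as.character(complex_id),
                   system_id = as.character(system_id),
                   dG_pred = as.numeric(dG_pred),
                   dG_pred_err = as.numeric(dG_pred_err),
                   dG_exp = as.numeric(dG_exp),
                   stringsAsFactors = FALSE)
  class(df) <- c("benchmark_table", "data.frame")
  df
}

#' Read a benchmark TSV
#'
#' Columns: `complex_id`, `system_id`, `dg_pred`, `dg_pred_err`, `dg_exp`.
#'
#' @param path Path to the TSV.
#' @return A [benchmark_table()].
#' @export
read_benchmark_table <- function(path) {
  abfe_assert(file.exists(path), sprintf("file not found: %s", path),
              "abfe_io_error")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  required <- c("complex_id", "system_id", "dg_pred", "dg_pred_err",
                "dg_exp")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abfe_stop(sprintf("benchmark table is missing column(s): %s",
                      paste(miss, collapse = ", ")), "abfe_format_error")
  }
  benchmark_table(df$complex_id, df$system_id, df$dg_pred, df$dg_pred_err,
                  df$dg_exp)
}

#' Per-system protein-conformational adjustment
#'
#' Systematic errors in predicted absolute binding free energies (dominated
#' by apo/holo conformational differences of the protein) are approximately
#' constant across ligands binding the same pocket. Where reference data
#' exist, the per-system mean signed error (MSE) of the raw predictions is
#' used as the empirical estimate of this term
#' (\eqn{\Delta G_{conf}^{prot}}), and predictions are adjusted by
#' subtracting it. After adjustment the per-system mean signed error is
#' zero by construction; the ranking of ligands within a system is
#' unchanged.
#'
#' Systems with fewer complexes than `min_complexes` are left unadjusted
#' (with a warning) since a one-point MSE would absorb the whole error.
#'
#' @param tbl A [benchmark_table()].
#' @param min_complexes Minimum complexes per system for adjustment
#'   (default 2).
#' @return List with `per_system` (named vector of
#'   \eqn{\Delta G_{conf}^{prot}} values; `NA` for skipped systems) and
#'   `adjusted` (the adjusted [benchmark_table()]).
#' @export
conf_correction <- function(tbl, min_complexes = 2L) {
  abfe_assert(inherits(tbl, "benchmark_table"),
              "tbl must be a benchmark_table", "abfe_domain_error")
  systems <- unique(tbl$system_id)
  per_system <- stats::setNames(rep(NA_real_, length(systems)), systems)
  adjusted <- tbl
  skipped <- character(0)
  for (s in systems) {
    rows <- tbl$system_id == s
    if (sum(rows) < min_complexes) {
      skipped <- c(skipped, s)
      next
    }
    mse <- mean(tbl$dG_pred[rows] - tbl$dG_exp[rows])
    per_system[s] <- mse
    adjusted$dG_pred[rows] <- adjusted$dG_pred[rows] - mse
  }
  if (length(skipped) > 0) {
    warning(sprintf(
      "system(s) %s have < %d complexes; left unadjusted",
      paste(skipped, collapse = ", "), min_complexes), call. = FALSE)
  }
  list(per_system = per_system, adjusted = adjusted)
}

#' Accuracy metrics with bootstrap uncertainties
#'
#' Mean unsigned error, root mean squared error, Pearson's r and
#' Spearman's ρ of predictions against reference values, with standard
#' errors from a nonparametric bootstrap over complexes (rows are
#' resampled with replacement, metrics recomputed, SD across resamples
#' reported). Also reports the percentage of complexes whose reported
#' prediction error exceeds each threshold.
#'
#' @param tbl A [benchmark_table()] with >= 3 rows.
#' @param n_boot Bootstrap resamples, >= 100 (default 1000).
#' @param seed Integer seed.
#' @param thresholds Thresholds (kcal/mol) for the error-bar fractions
#'   (default `c(0.5, 1.0)`).
#' @return An object of class `metrics_report` with fields `mue`, `rmse`,
#'   `pearson_r`, `spearman_rho` (each `c(value, stderr)`),
#'   `frac_stderr_gt` (percentages), `per_system`, and
#'   `correlation_defined`.
#' @export
accuracy_metrics <- function(tbl, n_boot = 1000, seed,
                             thresholds = c(0.5, 1.0)) {
  abfe_assert(inherits(tbl, "benchmark_table"),
              "tbl must be a benchmark_table", "abfe_domain_error")
  abfe_assert(nrow(tbl) >= 3, "need >= 3 complexes", "abfe_domain_error")
  abfe_assert(is_count(n_boot) && n_boot >= 100,
              "n_boot must be an integer >= 100", "abfe_parameter_error")
  abfe_assert(is_count(seed, min = 0L), "seed must be a non-negative integer",
              "abfe_parameter_error")

  corr_ok <- stats::var(tbl$dG_pred) > 0 && stats::var(tbl$dG_exp) > 0
  if (!corr_ok) {
    warning("zero variance in predictions or reference; ",
            "correlations are undefined", call. = FALSE)
  }
  point <- metric_values(tbl$dG_pred, tbl$dG_exp, corr_ok)

  n <- nrow(tbl)
  set.seed(derive_seed(seed, 1L))
  boots <- matrix(NA_real_, nrow = n_boot, ncol = 4L)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ok <- corr_ok && stats::var(tbl$dG_pred[idx]) > 0 &&
      stats::var(tbl$dG_exp[idx]) > 0
    boots[b, ] <- metric_values(tbl$dG_pred[idx], tbl$dG_exp[idx], ok)
  }
  ses <- apply(boots, 2, stats::sd, na.rm = TRUE)

  frac <- vapply(thresholds,
                 function(t) 100 * mean(tbl$dG_pred_err > t), 0)
  names(frac) <- paste0("gt_", thresholds)

  per_system <- lapply(split(seq_len(n), tbl$system_id), function(rows) {
    sub <- tbl[rows, , drop = FALSE]
    ok <- nrow(sub) >= 3 && stats::var(sub$dG_pred) > 0 &&
      stats::var(sub$dG_exp) > 0
    v <- metric_values(sub$dG_pred, sub$dG_exp, ok)
    list(n = nrow(sub), mue = v[1], rmse = v[2], pearson_r = v[3],
         spearman_rho = v[4])
  })

  structure(list(
    mue = c(value = point[1], stderr = ses[1]),
    rmse = c(value = point[2], stderr = ses[2]),
    pearson_r = c(value = point[3], stderr = ses[3]),
    spearman_rho = c(value = point[4], stderr = ses[4]),
    frac_stderr_gt = frac,
    per_system = per_system,
    correlation_defined = corr_ok,
    n = n, n_boot = n_boot, seed = seed
  ), class = "metrics_report")
}

metric_values <- function(pred, ref, corr_ok) {
  err <- pred - ref
  c(mean(abs(err)), sqrt(mean(err^2)),
    if (corr_ok) stats::cor(pred, ref) else NA_real_,
    if (corr_ok) stats::cor(pred, ref, method = "spearman") else NA_real_)
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(m) sprintf("%.3f(%.3f)", m["value"], m["stderr"])
  cat(sprintf(
    "<metrics_report> n = %d: MUE %s, RMSE %s kcal/mol; r %s, rho %s\n",
    x$n, fmt(x$mue), fmt(x$rmse), fmt(x$pearson_r), fmt(x$spearman_rho)))
  if (length(x$frac_stderr_gt)) {
    cat("  % complexes with prediction error bars above thresholds: ",
        paste(sprintf("%s: %.2f%%", sub("gt_", "> ",
                                        names(x$frac_stderr_gt)),
                      x$frac_stderr_gt), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
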