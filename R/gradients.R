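#' Gradient series at one λ-window from one replica
#'
#' Samples of the energy gradient with respect to the coupling parameter,
#' \eqn{\partial H/\partial\lambda} (kcal/mol), collected during one
#' equilibrium replica at a fixed λ.
#'
#' @param replica_id Integer replica identifier (1-based).
#' @param lambda λ value of the window.
#' @param samples Numeric vector of ∂H/∂λ samples, kcal/mol.
#' @param times Optional strictly increasing sample times in ps, same length
#'   as `samples`.
#' @return An object of class `gradient_series`.
#' @export
gradient_series <- function(replica_id, lambda, samples, times = NULL) {
  abfe_assert(is_count(replica_id), "replica_id must be an integer >= 1",
              "abfe_domain_error")
  abfe_assert(is_number(lambda) && lambda >= 0 && lambda <= 1,
              "lambda must lie in [0, 1]", "abfe_domain_error")
  abfe_assert(is.numeric(samples) && length(samples) >= 1L &&
                all(is.finite(samples)),
              "samples must be a non-empty finite numeric vector",
              "abfe_domain_error")
  if (!is.null(times)) {
    abfe_assert(is.numeric(times) && length(times) == length(samples),
                "times must match samples in length", "abfe_format_error")
    abfe_assert(all(diff(times) > 0), "times must be strictly increasing",
                "abfe_format_error")
  }
  structure(list(replica_id = as.integer(replica_id), lambda = lambda,
                 samples = as.numeric(samples),
                 times = if (is.null(times)) NULL else as.numeric(times)),
            class = "gradient_series")
}

#' Replica-resolved gradients for one alchemical leg
#'
#' Holds one [gradient_series()] per (λ, replica) cell of a rectangular grid:
#' every λ of the schedule must be covered by every replica. Rectangularity
#' is what makes ensemble averaging across replicas well defined at each
#' window.
#'
#' @param leg One of `"complex_alchemical"`, `"complex_restraints"`,
#'   `"ligand_alchemical"`.
#' @param schedule A [lambda_schedule()].
#' @param series List of [gradient_series()] covering the grid.
#' @return An object of class `ensemble_gradients` with fields `leg`,
#'   `schedule`, `series`, and `replica_ids`.
#' @export
ensemble_gradients <- function(leg, schedule, series) {
  abfe_assert(is.character(leg) && length(leg) == 1L &&
                leg %in% c("complex_alchemical", "complex_restraints",
                           "ligand_alchemical"),
              "unknown leg label", "abfe_domain_error")
  abfe_assert(inherits(schedule, "lambda_schedule"),
              "schedule must be a lambda_schedule", "abfe_domain_error")
  abfe_assert(is.list(series) && length(series) > 0 &&
                all(vapply(series, inherits, TRUE, "gradient_series")),
              "series must be a non-empty list of gradient_series",
              "abfe_domain_error")

  lam <- vapply(series, function(s) s$lambda, 0)
  rep_id <- vapply(series, function(s) s$replica_id, 0L)
  replica_ids <- sort(unique(rep_id))

  # match series lambdas onto the schedule within tolerance
  idx <- match_lambda(lam, schedule$values)
  bad <- which(is.na(idx))
  if (length(bad) > 0) {
    abfe_stop(sprintf(
      "lambda value(s) %s not found in schedule '%s' (tolerance 1e-9)",
      paste(unique(format(lam[bad])), collapse = ", "), schedule$name),
      "abfe_schedule_mismatch_error")
  }
  key <- paste(idx, rep_id)
  abfe_assert(!anyDuplicated(key),
              "duplicate (lambda, replica) series", "abfe_format_error")

  expected <- expand.grid(k = seq_along(schedule$values), r = replica_ids)
  missing <- !paste(expected$k, expected$r) %in% key
  if (any(missing)) {
    miss <- expected[missing, , drop = FALSE]
    abfe_stop(sprintf(
      "gradient grid is not rectangular; missing (lambda, replica) pairs: %s",
      paste(sprintf("(%g, %d)", schedule$values[miss$k], miss$r),
            collapse = ", ")),
      "abfe_completeness_error")
  }

  ord <- order(idx, rep_id)
  structure(list(leg = leg, schedule = schedule, series = series[ord],
                 replica_ids = as.integer(replica_ids)),
            class = "ensemble_gradients")
}

# nearest-match of lambda values onto schedule values within 1e-9
match_lambda <- function(lam, sched_values, tol = 1e-9) {
  vapply(lam, function(x) {
    d <- abs(sched_values - x)
    k <- which.min(d)
    if (d[k] <= tol) k else NA_integer_
  }, 0L)
}

#' Extract the series of one λ-window
#'
#' @param x An [ensemble_gradients()] object.
#' @param lambda λ value (matched to the schedule within 1e-9).
#' @return List of [gradient_series()], one per replica, ordered by replica
#'   id.
#' @export
series_at_lambda <- function(x, lambda) {
  abfe_assert(inherits(x, "ensemble_gradients"),
              "x must be ensemble_gradients", "abfe_domain_error")
  k <- match_lambda(lambda, x$schedule$values)
  abfe_assert(!is.na(k), "lambda not in schedule",
              "abfe_schedule_mismatch_error")
  Filter(function(s) abs(s$lambda - x$schedule$values[k]) <= 1e-9, x$series)
}

#' @export
print.ensemble_gradients <- function(x, ...) {
  n <- vapply(x$series, function(s) length(s$samples), 0L)
  cat(sprintf(
    "<ensemble_gradients> leg %s: %d lambda-windows x %d replicas, %d samples/window (median)\n",
    x$leg, length(x$schedule$values), length(x$replica_ids),
    as.integer(stats::median(n))))
  invisible(x)
}

#' Read a canonical gradient table
#'
#' Reads the package's engine-agnostic TSV format for per-λ, per-replica
#' gradient samples: tab-separated columns `lambda`, `replica`, `time_ps`,
#' `dhdl_kcal_mol`, with `#`-prefixed metadata lines ignored. λ values in
#' the file must each match a schedule window within 1e-9, and the
#' (λ, replica) grid must be rectangular.
#'
#' @param path Path to the TSV file.
#' @param leg Leg label, see [ensemble_gradients()].
#' @param schedule A [lambda_schedule()].
#' @return An [ensemble_gradients()] object.
#' @seealso [write_gradient_table()]
#' @export
read_gradient_table <- function(path, leg, schedule) {
  abfe_assert(file.exists(path), sprintf("file not found: %s", path),
              "abfe_io_error")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  required <- c("lambda", "replica", "time_ps", "dhdl_kcal_mol")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abfe_stop(sprintf("gradient table is missing column(s): %s",
                      paste(miss, collapse = ", ")), "abfe_format_error")
  }
  grp <- split(df, list(df$lambda, df$replica), drop = TRUE)
  series <- lapply(grp, function(g) {
    g <- g[order(g$time_ps), , drop = FALSE]
    gradient_series(replica_id = g$replica[1], lambda = g$lambda[1],
                    samples = g$dhdl_kcal_mol, times = g$time_ps)
  })
  ensemble_gradients(leg = leg, schedule = schedule,
                     series = unname(series))
}

#' Write a canonical gradient table
#'
#' Inverse of [read_gradient_table()]; values round-trip within 1e-12 (17
#' significant digits are written).
#'
#' @param x An [ensemble_gradients()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gradient_table <- function(x, path) {
  abfe_assert(inherits(x, "ensemble_gradients"),
              "x must be ensemble_gradients", "abfe_domain_error")
  rows <- lapply(x$series, function(s) {
    times <- if (is.null(s$times)) seq_along(s$samples) * 2.0 else s$times
    data.frame(lambda = s$lambda, replica = s$replica_id, time_ps = times,
               dhdl_kcal_mol = s$samples)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#leg=%s", x$leg), con)
  writeLines(sprintf("#schedule=%s", x$schedule$name), con)
  writeLines(paste(c("lambda", "replica", "time_ps", "dhdl_kcal_mol"),
                   collapse = "\t"), con)
  writeLines(sprintf("%.17g\t%d\t%.17g\t%.17g",
                     df$lambda, df$replica, df$time_ps, df$dhdl_kcal_mol),
             con)
  invisible(path)
}
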