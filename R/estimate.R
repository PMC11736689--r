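#' Free-energy estimate
#'
#' A ΔG value (kcal/mol) with its standard error, the estimator that
#' produced it, the number of replicas behind the uncertainty, and free-form
#' provenance.
#'
#' @param value ΔG in kcal/mol.
#' @param stderr Standard error in kcal/mol, >= 0.
#' @param method One of `"TI"`, `"BAR_MLE"`, `"JARZYNSKI"`, `"SUM"`,
#'   `"ANALYTIC"`.
#' @param n_replicas Number of replicas the estimate rests on (>= 1).
#' @param meta Optional provenance list.
#' @return An object of class `free_energy_estimate`.
#' @export
free_energy_estimate <- function(value, stderr, method,
                                 n_replicas = 1L, meta = list()) {
  abfe_assert(is_number(value), "value must be a finite number",
              "abfe_numeric_error")
  abfe_assert(is_number(stderr) && stderr >= 0,
              "stderr must be a finite number >= 0", "abfe_numeric_error")
  abfe_assert(is.character(method) && length(method) == 1L &&
                method %in% c("TI", "BAR_MLE", "JARZYNSKI", "SUM",
                              "ANALYTIC"),
              "unknown method tag", "abfe_domain_error")
  abfe_assert(is_count(n_replicas), "n_replicas must be an integer >= 1",
              "abfe_domain_error")
  structure(list(value = value, stderr = stderr, method = method,
                 n_replicas = as.integer(n_replicas), meta = meta),
            class = "free_energy_estimate")
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("<free_energy_estimate> %s: %.4f +/- %.4f kcal/mol (%d replicas)\n",
              x$method, x$value, x$stderr, x$n_replicas))
  invisible(x)
}

#' Components of the double-decoupling cycle
#'
#' The five ΔG terms entering the absolute binding free energy: the
#' alchemical and restraint legs in the complex, the alchemical leg of the
#' ligand in solvent, the analytic restraint-imposition term of the
#' decoupled ligand, and the empirical protein-conformational term.
#' `dG_conf_prot` may be 0, in which case the cycle is flagged
#' `"unadjusted"`.
#'
#' Components may be given as [free_energy_estimate()] objects or bare
#' numbers (bare numbers get stderr 0).
#'
#' @param dG_alch_com Alchemical (coupling) leg in the complex, kcal/mol.
#' @param dG_restr_com Restraint-release leg in the complex (0 when the
#'   combined coupling+release leg is used), kcal/mol.
#' @param dG_alch_lig Alchemical (decoupling) leg of the ligand in solvent,
#'   kcal/mol.
#' @param dG_restr_lig Analytic restraint term for the decoupled ligand,
#'   kcal/mol.
#' @param dG_conf_prot Protein-conformational adjustment, kcal/mol
#'   (default 0, flagged unadjusted).
#' @return An object of class `cycle_components`.
#' @seealso [assemble_cycle()], [boresch_restraint_dg()]
#' @export
cycle_components <- function(dG_alch_com, dG_restr_com, dG_alch_lig,
                             dG_restr_lig, dG_conf_prot = 0) {
  as_fee <- function(x, tag) {
    if (inherits(x, "free_energy_estimate")) return(x)
    abfe_assert(is_number(x), sprintf("%s must be a number or estimate", tag),
                "abfe_domain_error")
    free_energy_estimate(x, 0, "ANALYTIC")
  }
  comps <- list(dG_alch_com = as_fee(dG_alch_com, "dG_alch_com"),
                dG_restr_com = as_fee(dG_restr_com, "dG_restr_com"),
                dG_alch_lig = as_fee(dG_alch_lig, "dG_alch_lig"),
                dG_restr_lig = as_fee(dG_restr_lig, "dG_restr_lig"),
                dG_conf_prot = as_fee(dG_conf_prot, "dG_conf_prot"))
  comps$adjusted <- !(comps$dG_conf_prot$value == 0 &&
                        comps$dG_conf_prot$stderr == 0)
  structure(comps, class = "cycle_components")
}

#' @export
print.cycle_components <- function(x, ...) {
  cat("<cycle_components> (kcal/mol)\n")
  for (nm in c("dG_alch_com", "dG_restr_com", "dG_alch_lig",
               "dG_restr_lig", "dG_conf_prot")) {
    cat(sprintf("  %-13s %8.4f +/- %.4f\n", nm, x[[nm]]$value,
                x[[nm]]$stderr))
  }
  if (!x$adjusted) cat("  (unadjusted: dG_conf_prot = 0)\n")
  invisible(x)
}
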