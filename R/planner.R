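#' ABFE protocol specification
#'
#' All tunable protocol parameters for one ABFE prediction, per leg
#' (`complex` and `ligand`). For the equilibrium (EQ) method a leg carries
#' an ensemble size, a replica length (ns) and a λ-window count; for the
#' nonequilibrium (NEQ) method it carries the end-state ensemble size,
#' replica length, transitions per replica, and forward/reverse transition
#' lengths (ps). In NEQ, the restraint-release leg is costed equal to the
#' complex alchemical leg when `neq_restraint_leg_equals_complex` is set;
#' the EQ protocols here use the combined coupling+release leg, so no
#' separate restraint cost arises.
#'
#' @param method `"EQ"` or `"NEQ"`.
#' @param complex,ligand Per-leg parameter lists with fields
#'   `ensemble_size`, `replica_length` (ns), and either `n_lambda` (EQ) or
#'   `trns_per_rep`, `trans_len_fwd`, `trans_len_rev` (ps; NEQ).
#' @param neq_restraint_leg_equals_complex Cost the NEQ restraint leg like
#'   the complex leg (default `TRUE` for NEQ).
#' @param name Optional label.
#' @return An object of class `protocol_spec`.
#' @seealso [recommended_protocol()], [protocol_cost()]
#' @export
protocol_spec <- function(method, complex, ligand,
                          neq_restraint_leg_equals_complex = (method == "NEQ"),
                          name = "custom") {
  abfe_assert(method %in% c("EQ", "NEQ"), "method must be EQ or NEQ",
              "abfe_spec_error")
  check_leg <- function(leg, label) {
    abfe_assert(is.list(leg), sprintf("%s leg must be a list", label),
                "abfe_spec_error")
    abfe_assert(is_count(leg$ensemble_size),
                sprintf("%s ensemble_size must be an integer >= 1", label),
                "abfe_spec_error")
    abfe_assert(is_number(leg$replica_length) && leg$replica_length > 0,
                sprintf("%s replica_length must be > 0 ns", label),
                "abfe_spec_error")
    if (method == "EQ") {
      abfe_assert(is_count(leg$n_lambda),
                  sprintf("%s n_lambda is required for EQ", label),
                  "abfe_spec_error")
    } else {
      abfe_assert(is_count(leg$trns_per_rep),
                  sprintf("%s trns_per_rep is required for NEQ", label),
                  "abfe_spec_error")
      for (f in c("trans_len_fwd", "trans_len_rev")) {
        abfe_assert(is_number(leg[[f]]) && leg[[f]] > 0,
                    sprintf("%s %s must be > 0 ps for NEQ", label, f),
                    "abfe_spec_error")
      }
    }
    leg
  }
  structure(list(method = method,
                 complex = check_leg(complex, "complex"),
                 ligand = check_leg(ligand, "ligand"),
                 neq_restraint_leg_equals_complex =
                   isTRUE(neq_restraint_leg_equals_complex),
                 name = name),
            class = "protocol_spec")
}

#' Recommended ABFE protocols
#'
#' The recommended parameter values: the `standard` protocol uses ensemble
#' size 10 for the complex and 5 for the ligand in water, 10 ns replicas,
#' and — for NEQ — 50 transitions per replica (launched every 200 ps) with
#' 800 ps forward transitions for the complex and 400 ps in all other
#' cases. The `minimum` protocol (for resource-limited screening; not to be
#' undercut) uses ensemble size 5/5, 5 ns replicas and 25 transitions per
#' replica with the same transition lengths. EQ λ-window counts are 15 for
#' the combined complex leg and 13 for the ligand leg.
#'
#' @param profile `"standard"` or `"minimum"`.
#' @param method `"EQ"` or `"NEQ"`.
#' @return A [protocol_spec()].
#' @examples
#' protocol_cost(recommended_protocol("standard", "EQ"))
#' @export
recommended_protocol <- function(profile = c("standard", "minimum"),
                                 method = c("EQ", "NEQ")) {
  if (!is.character(profile) || length(profile) != 1L ||
      !profile %in% c("standard", "minimum")) {
    abfe_stop(sprintf("unknown profile '%s'",
                      paste(profile, collapse = ",")), "abfe_lookup_error")
  }
  method <- match.arg(method)
  es_com <- if (profile == "standard") 10L else 5L
  es_lig <- 5L
  rep_len <- if (profile == "standard") 10 else 5
  tpr <- if (profile == "standard") 50L else 25L
  if (method == "EQ") {
    protocol_spec("EQ",
      complex = list(ensemble_size = es_com, replica_length = rep_len,
                     n_lambda = 15L),
      ligand = list(ensemble_size = es_lig, replica_length = rep_len,
                    n_lambda = 13L),
      name = sprintf("%s_EQ", profile))
  } else {
    protocol_spec("NEQ",
      complex = list(ensemble_size = es_com, replica_length = rep_len,
                     trns_per_rep = tpr, trans_len_fwd = 800,
                     trans_len_rev = 400),
      ligand = list(ensemble_size = es_lig, replica_length = rep_len,
                    trns_per_rep = tpr, trans_len_fwd = 400,
                    trans_len_rev = 400),
      name = sprintf("%s_NEQ", profile))
  }
}

#' Simulation-time cost of a protocol
#'
#' Per-leg aggregate simulation time for one ABFE prediction. EQ legs cost
#' `n_lambda * ensemble_size * replica_length` ns; NEQ legs cost the two
#' end-state ensembles (`2 * ensemble_size * replica_length`) plus the
#' transitions in each direction
#' (`trns_per_rep * ensemble_size * trans_len`, ps converted to ns). The
#' NEQ restraint leg is costed equal to the complex alchemical leg when
#' `neq_restraint_leg_equals_complex` is set; EQ protocols using the
#' combined leg carry no separate restraint cost.
#'
#' @param spec A [protocol_spec()].
#' @return An object of class `cost_breakdown` with per-leg times in ns
#'   (`complex_alchemical`, `complex_restraints`, `ligand_alchemical`) and
#'   `overall` in μs.
#' @export
protocol_cost <- function(spec) {
  abfe_assert(inherits(spec, "protocol_spec"),
              "spec must be a protocol_spec", "abfe_spec_error")
  leg_cost <- function(leg) {
    if (spec$method == "EQ") {
      leg$n_lambda * leg$ensemble_size * leg$replica_length
    } else {
      2 * leg$ensemble_size * leg$replica_length +
        leg$trns_per_rep * leg$ensemble_size * leg$trans_len_fwd / 1000 +
        leg$trns_per_rep * leg$ensemble_size * leg$trans_len_rev / 1000
    }
  }
  com <- leg_cost(spec$complex)
  lig <- leg_cost(spec$ligand)
  restr <- if (spec$method == "NEQ" &&
               spec$neq_restraint_leg_equals_complex) com else 0
  structure(list(complex_alchemical = com,
                 complex_restraints = restr,
                 ligand_alchemical = lig,
                 overall = (com + restr + lig) / 1000),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "<cost_breakdown> complex %g ns, restraints %g ns, ligand %g ns; overall %g us\n",
    x$complex_alchemical, x$complex_restraints, x$ligand_alchemical,
    x$overall))
  invisible(x)
}

#' Escalation state for the reliability-driven protocol workflow
#'
#' Wraps a [protocol_spec()] together with the history of parameter
#' escalations applied so far. Use [escalation_step()] to advance the
#' state when an estimate fails the reliability criteria.
#'
#' @param spec A [protocol_spec()].
#' @param caps Named list of caps:
#'   `trns_per_rep_steps` (default `c(50, 75, 100)`),
#'   `trans_len_fwd_steps` (ps, default `c(800, 1000, 2000)`),
#'   `ensemble_increment` (default 5), `ensemble_cap` (default 100),
#'   `replica_length_cap` (ns, default 100), `trans_len_rev_floor`
#'   (ps, default 400).
#' @return An object of class `escalation_state` with fields `spec`,
#'   `step_history`, `exhausted`, `complete`, and `caps`.
#' @export
escalation_state <- function(spec, caps = list()) {
  abfe_assert(inherits(spec, "protocol_spec"),
              "spec must be a protocol_spec", "abfe_spec_error")
  defaults <- list(trns_per_rep_steps = c(50L, 75L, 100L),
                   trans_len_fwd_steps = c(800, 1000, 2000),
                   ensemble_increment = 5L,
                   ensemble_cap = 100L,
                   replica_length_cap = 100,
                   trans_len_rev_floor = 400)
  caps <- utils::modifyList(defaults, caps)
  structure(list(spec = spec, step_history = list(), exhausted = FALSE,
                 complete = FALSE, caps = caps, note = NULL),
            class = "escalation_state")
}

#' One step of the reliability-driven escalation
#'
#' Implements the recommended stepwise workflow for complexes that fail
#' one or both reliability criteria (standard error and, for NEQ,
#' distance): adjust one parameter at a time in a fixed order, re-running
#' and filtering out complexes that pass after each step. For NEQ the
#' order is (1) transitions per replica through 50 → 75 → 100 (distances
#' are most sensitive to this parameter), (2) forward transition length
#' through 800 ps → 1 ns → 2 ns (reverse scaled to half, floored at
#' 400 ps), (3) ensemble size +5 per step up to 100, (4) replica length
#' doubled up to 100 ns. For EQ: ensemble size first, then replica
#' length. When every parameter is capped the state is marked exhausted
#' with a note that some systems may need to breach even these maxima.
#'
#' Escalated NEQ transitions cannot reuse earlier ones: transitions must
#' be rerun from scratch, so the cost of each step is the full new
#' protocol cost.
#'
#' @param state An [escalation_state()].
#' @param flags List with `precision_ok` and `overlap_ok` (as from
#'   [reliability_flags()]; `overlap_ok` may be `NA` for EQ).
#' @return The updated `escalation_state`.
#' @export
escalation_step <- function(state, flags) {
  abfe_assert(inherits(state, "escalation_state"),
              "state must be an escalation_state", "abfe_spec_error")
  if (state$exhausted) {
    abfe_stop("escalation state is exhausted", "abfe_state_error")
  }
  ok <- isTRUE(flags$precision_ok) &&
    (is.null(flags$overlap_ok) || is.na(flags$overlap_ok) ||
       isTRUE(flags$overlap_ok))
  if (ok) {
    state$complete <- TRUE
    return(state)
  }

  spec <- state$spec
  caps <- state$caps
  bump <- NULL

  if (spec$method == "NEQ") {
    steps <- caps$trns_per_rep_steps
    cur <- spec$complex$trns_per_rep
    nxt <- steps[steps > cur]
    if (length(nxt) > 0) {
      bump <- list(parameter = "trns_per_rep", old = cur, new = nxt[1])
      spec$complex$trns_per_rep <- as.integer(nxt[1])
      spec$ligand$trns_per_rep <- as.integer(nxt[1])
    }
    if (is.null(bump)) {
      steps <- caps$trans_len_fwd_steps
      cur <- spec$complex$trans_len_fwd
      nxt <- steps[steps > cur]
      if (length(nxt) > 0) {
        bump <- list(parameter = "trans_len_fwd", old = cur, new = nxt[1])
        spec$complex$trans_len_fwd <- nxt[1]
        spec$complex$trans_len_rev <- max(nxt[1] / 2,
                                          caps$trans_len_rev_floor)
        spec$ligand$trans_len_fwd <- max(nxt[1] / 2,
                                         caps$trans_len_rev_floor)
        spec$ligand$trans_len_rev <- spec$ligand$trans_len_fwd
      }
    }
  }
  if (is.null(bump)) {
    cur <- spec$complex$ensemble_size
    if (cur < caps$ensemble_cap) {
      new <- min(cur + caps$ensemble_increment, caps$ensemble_cap)
      bump <- list(parameter = "ensemble_size", old = cur, new = new)
      spec$complex$ensemble_size <- as.integer(new)
    }
  }
  if (is.null(bump)) {
    cur <- spec$complex$replica_length
    if (cur < caps$replica_length_cap) {
      new <- min(cur * 2, caps$replica_length_cap)
      bump <- list(parameter = "replica_length", old = cur, new = new)
      spec$complex$replica_length <- new
      spec$ligand$replica_length <- new
    }
  }

  if (is.null(bump)) {
    state$exhausted <- TRUE
    state$note <- paste(
      "all escalation parameters are at their recommended maxima;",
      "some systems may need to breach even these values")
    return(state)
  }
  state$spec <- spec
  state$step_history <- c(state$step_history, list(bump))
  state
}

#' @export
print.escalation_state <- function(x, ...) {
  cat(sprintf("<escalation_state> %s, %d step(s)%s%s\n",
              x$spec$name, length(x$step_history),
              if (x$complete) ", complete" else "",
              if (x$exhausted) ", exhausted" else ""))
  for (h in x$step_history) {
    cat(sprintf("  %s: %g -> %g\n", h$parameter, h$old, h$new))
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
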