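#' Bidirectional nonequilibrium work set
#'
#' Stores the work values (kcal/mol) of fast alchemical transitions, each
#' tagged with its direction and the end-state replica it was launched from.
#' Forward transitions run λ 0→1, reverse transitions 1→0; stored work is
#' the work done on the system along its own transition direction, so the
#' Crooks pairing compares forward works against *negated* reverse works.
#'
#' @param direction Character vector, each `"forward"` or `"reverse"`.
#' @param replica_id Integer vector of originating end-state replicas.
#' @param work Numeric vector of work values, kcal/mol.
#' @param transition_length_fwd,transition_length_rev Transition lengths in
#'   ps (metadata; default `NA`).
#' @return An object of class `work_set`: a list with a data frame
#'   `records` (`direction`, `replica_id`, `work`) plus the transition
#'   lengths and a `meta` list.
#' @export
work_set <- function(direction, replica_id, work,
                     transition_length_fwd = NA_real_,
                     transition_length_rev = NA_real_) {
  n <- length(work)
  abfe_assert(length(direction) == n && length(replica_id) == n,
              "direction, replica_id and work must have equal length",
              "abfe_format_error")
  abfe_assert(all(direction %in% c("forward", "reverse")),
              "direction must be 'forward' or 'reverse'",
              "abfe_format_error")
  abfe_assert(is.numeric(work) && all(is.finite(work)),
              "work values must be finite numbers", "abfe_domain_error")
  records <- data.frame(direction = as.character(direction),
                        replica_id = as.integer(replica_id),
                        work = as.numeric(work),
                        stringsAsFactors = FALSE)
  n_fwd <- sum(records$direction == "forward")
  n_rev <- sum(records$direction == "reverse")
  structure(list(records = records,
                 transition_length_fwd = transition_length_fwd,
                 transition_length_rev = transition_length_rev,
                 meta = list(n_fwd = n_fwd, n_rev = n_rev,
                             unidirectional = (n_fwd == 0L || n_rev == 0L))),
            class = "work_set")
}

#' Forward / reverse work values of a work set
#'
#' @param ws A [work_set()].
#' @return Numeric vector of work values, kcal/mol.
#' @export
forward_works <- function(ws) {
  ws$records$work[ws$records$direction == "forward"]
}

#' @rdname forward_works
#' @export
reverse_works <- function(ws) {
  ws$records$work[ws$records$direction == "reverse"]
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf(
    "<work_set> %d forward + %d reverse works (%d replicas); transitions %s/%s ps\n",
    x$meta$n_fwd, x$meta$n_rev, length(unique(x$records$replica_id)),
    format(x$transition_length_fwd), format(x$transition_length_rev)))
  invisible(x)
}

#' Read a canonical work table
#'
#' TSV with header columns `direction`, `replica`, `work_kcal_mol` and the
#' metadata lines `#trans_len_fwd_ps=` and `#trans_len_rev_ps=`. A file with
#' records in only one direction is accepted but flagged as unidirectional
#' (with a warning): the bidirectional estimator will refuse it.
#'
#' @param path Path to the TSV file.
#' @return A [work_set()].
#' @seealso [write_work_table()]
#' @export
read_work_table <- function(path) {
  abfe_assert(file.exists(path), sprintf("file not found: %s", path),
              "abfe_io_error")
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^#", key, "="), meta_lines, value = TRUE)
    if (length(m) == 0) return(NA_real_)
    v <- sub(paste0("^#", key, "="), "", m[1])
    if (v %in% c("NA", "nan", "NaN")) return(NA_real_)
    as.numeric(v)
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t", check.names = FALSE)
  required <- c("direction", "replica", "work_kcal_mol")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abfe_stop(sprintf("work table is missing column(s): %s",
                      paste(miss, collapse = ", ")), "abfe_format_error")
  }
  bad <- setdiff(unique(df$direction), c("forward", "reverse"))
  if (length(bad) > 0) {
    abfe_stop(sprintf("unknown direction token(s): %s",
                      paste(bad, collapse = ", ")), "abfe_format_error")
  }
  ws <- work_set(df$direction, df$replica, df$work_kcal_mol,
                 transition_length_fwd = get_meta("trans_len_fwd_ps"),
                 transition_length_rev = get_meta("trans_len_rev_ps"))
  if (ws$meta$unidirectional) {
    warning("work table holds records in only one direction; ",
            "bidirectional estimation is unavailable", call. = FALSE)
  }
  ws
}

#' Write a canonical work table
#'
#' Inverse of [read_work_table()]; works round-trip within 1e-12.
#'
#' @param ws A [work_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_work_table <- function(ws, path) {
  abfe_assert(inherits(ws, "work_set"), "ws must be a work_set",
              "abfe_domain_error")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#trans_len_fwd_ps=%.17g", ws$transition_length_fwd),
             con)
  writeLines(sprintf("#trans_len_rev_ps=%.17g", ws$transition_length_rev),
             con)
  writeLines("direction\treplica\twork_kcal_mol", con)
  r <- ws$records
  writeLines(sprintf("%s\t%d\t%.17g", r$direction, r$replica_id, r$work),
             con)
  invisible(path)
}

#' Remove extreme work values
#'
#' Nonequilibrium coupling transitions occasionally produce extreme work
#' values (notably in the forward direction when the ligand is coupled in
#' the protein environment); these compromise accuracy and precision, so all
#' work values above the cutoff are discarded before estimation. The default
#' cutoff is 1000 kcal/mol. The operation is idempotent.
#'
#' @param ws A [work_set()].
#' @param cutoff Positive cutoff in kcal/mol; records with `work > cutoff`
#'   are removed. Default 1000.
#' @return List with `filtered` (the filtered [work_set()]),
#'   `n_removed_fwd`, and `n_removed_rev`.
#' @export
filter_extreme_work <- function(ws, cutoff = 1000) {
  abfe_assert(inherits(ws, "work_set"), "ws must be a work_set",
              "abfe_domain_error")
  abfe_assert(is_number(cutoff) && cutoff > 0, "cutoff must be > 0",
              "abfe_parameter_error")
  r <- ws$records
  drop <- r$work > cutoff
  n_removed_fwd <- sum(drop & r$direction == "forward")
  n_removed_rev <- sum(drop & r$direction == "reverse")
  keep <- r[!drop, , drop = FALSE]
  for (d in c("forward", "reverse")) {
    had <- any(r$direction == d)
    if (had && !any(keep$direction == d)) {
      abfe_stop(sprintf(
        "extreme-work filter removed every %s record (cutoff %g kcal/mol)",
        d, cutoff), "abfe_emptiness_error")
    }
  }
  filtered <- work_set(keep$direction, keep$replica_id, keep$work,
                       transition_length_fwd = ws$transition_length_fwd,
                       transition_length_rev = ws$transition_length_rev)
  filtered$meta$extreme_cutoff <- cutoff
  list(filtered = filtered, n_removed_fwd = n_removed_fwd,
       n_removed_rev = n_removed_rev)
}
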