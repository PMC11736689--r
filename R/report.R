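#' Write a structured JSON report
#'
#' Serializes an estimate or diagnostics bundle to JSON (UTF-8, snake_case
#' keys), adding the package version. Classed objects
#' ([free_energy_estimate()], [cycle_components()], diagnostics and metrics
#' reports, protocol specs) are flattened to plain lists; the class name is
#' stored under `"_class"` so the bundle can be re-read.
#'
#' NaN or infinite numbers anywhere in the bundle are a validation error:
#' reports must only carry numbers that downstream tooling can consume.
#'
#' @param results A serializable bundle (classed object or plain list).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_report()]
#' @export
write_report <- function(results, path) {
  payload <- list(
    software = "abfetools",
    version = as.character(utils::packageVersion("abfetools")),
    results = strip_classes(results)
  )
  check_finite(payload$results, "results")
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abfe_stop(sprintf("cannot write report to '%s'", path),
                     "abfe_io_error")
  invisible(path)
}

#' Read a structured JSON report
#'
#' @param path Path written by [write_report()].
#' @return The deserialized `results` bundle (plain lists; `"_class"`
#'   entries record the original classes).
#' @export
read_report <- function(path) {
  abfe_assert(file.exists(path), sprintf("file not found: %s", path),
              "abfe_io_error")
  jsonlite::read_json(path, simplifyVector = TRUE)$results
}

strip_classes <- function(x) {
  if (is.list(x)) {
    out <- lapply(x, strip_classes)
    cls <- class(x)[1]
    if (cls != "list" && cls != "data.frame") out[["_class"]] <- cls
    if (is.data.frame(x)) out <- x
    out
  } else if (is.atomic(x) && !is.null(names(x)) && length(x) > 0) {
    as.list(x)  # keep names as JSON object keys
  } else {
    x
  }
}

check_finite <- function(x, where) {
  if (is.list(x)) {
    nms <- names(x) %||% rep("", length(x))
    for (i in seq_along(x)) {
      check_finite(x[[i]],
                   if (nzchar(nms[i])) paste0(where, "$", nms[i]) else where)
    }
  } else if (is.numeric(x) && any(!is.finite(x))) {
    abfe_stop(sprintf("non-finite number in report field '%s'", where),
              "abfe_validation_error")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
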