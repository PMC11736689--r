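# internal helpers shared across the package

# classed conditions so callers/tests can match on failure mode rather than
# message text
abfe_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "abfe_error")))
}

abfe_assert <- function(ok, msg, class) {
  if (!isTRUE(ok)) abfe_stop(msg, class)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Deterministic sub-seed derivation. Streams are keyed to small integer
# coordinates (e.g. lambda index, sorted replica position) so that relabelling
# replicas does not change the seed stream. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) h <- (h * 69069 + (k %% 2147483647) + 1) %% 2147483629
  as.integer(h %% 2147483629) + 1L
}

# mean of exp(x) computed through the log-sum-exp trick; returns list with
# log-mean and the stabilized weights (used for delta-method errors)
logmeanexp <- function(x) {
  m <- max(x)
  w <- exp(x - m)
  list(logmean = m + log(mean(w)), weights = w)
}
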