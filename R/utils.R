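# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# Probability vectors used by the synthetic generator must be exact
# distributions: non-negative and summing to 1 within 1e-12.
check_prob_vector <- function(p, what) {
  if (length(p) == 0 || any(!is.finite(p)) || any(p < 0))
    stop_input("invalid probability vector for '", what,
               "': entries must be finite and non-negative")
  if (abs(sum(p) - 1) > 1e-12)
    stop_input("probabilities for '", what, "' must sum to 1 (got ",
               format(sum(p), digits = 17), ")")
  invisible(p)
}

# Adler-32 checksum of a string; used for config digests. Pure R so the
# digest is stable across platforms and sessions.
adler32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  a <- 1L
  b <- 0L
  for (byte in bytes) {
    a <- (a + byte) %% 65521L
    b <- (b + a) %% 65521L
  }
  sprintf("%04x%04x", b, a)
}

# Central-difference Jacobian of a vector-valued function; used for the
# observed information (Jacobian of the analytic score). Symmetrized by
# the caller where a Hessian is expected.
num_jacobian <- function(fn, x, eps = 1e-5) {
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}
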