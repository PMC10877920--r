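# Log-likelihood of the dependent double-hurdle model.
#
# Linear variant (amounts on the observed scale):
#   zero:     log[ 1 - Phi2(z'theta, X'beta/sigma; rho) ]
#   positive: log Phi( (z'theta + (rho/sigma)(y - X'beta)) / sqrt(1-rho^2) )
#             + log phi((y - X'beta)/sigma) - log sigma
# Exponential variant (amounts lognormal): exp(X'beta + v) is positive for
# any v, so the amount hurdle is always passed and zeros arise from the
# participation hurdle alone:
#   zero:     log[ 1 - Phi(z'theta) ]
#   positive: same as linear with y replaced by log y, minus log y (Jacobian).
# With rho = 0 the likelihood factorizes into a participation part and a
# conditional-amount part (see dh_loglik_parts()).

# Likelihood terms are floored at this value before taking logs so a far
# tail never produces -Inf; floored terms are counted in diagnostics.
.dh_floor <- 1e-300

dh_index <- function(params, dm) {
  list(q = drop(dm$z %*% params$theta),
       m = drop(dm$X %*% params$beta))
}

#' Double-hurdle log-likelihood
#'
#' Evaluates the log-likelihood of the dependent double-hurdle model at
#' `params` for the data in `dm`. See [dh_parameters()] for the model and
#' the package vignette for the likelihood in full.
#'
#' @param params a [dh_parameters()] object.
#' @param dm a `dh_design` with non-negative outcome `y`.
#' @param by_observation logical; return the n per-observation
#'   contributions instead of their sum.
#' @return scalar log-likelihood (or a vector of contributions), with
#'   attribute `"n_floored"` counting likelihood terms floored at 1e-300
#'   before the log.
#' @export
dh_loglik <- function(params, dm, by_observation = FALSE) {
  check_params_design(params, dm)
  if (is.null(dm$y)) stop_input("design has no outcome vector 'y'")
  y <- dm$y
  idx <- dh_index(params, dm)
  q <- idx$q
  m <- idx$m
  sigma <- params$sigma
  rho <- params$rho
  s <- sqrt(1 - rho^2)
  pos <- y > 0
  ll <- numeric(length(y))
  n_floored <- 0L
  if (any(!pos)) {
    p0 <- if (params$variant == "linear")
      1 - pbnorm2(q[!pos], m[!pos] / sigma, rho)
    else
      stats::pnorm(q[!pos], lower.tail = FALSE)
    n_floored <- n_floored + sum(p0 < .dh_floor)
    ll[!pos] <- log(pmax(p0, .dh_floor))
  }
  if (any(pos)) {
    ystar <- if (params$variant == "linear") y[pos] else log(y[pos])
    r <- (ystar - m[pos]) / sigma
    A <- (q[pos] + rho * r) / s
    PA <- stats::pnorm(A)
    n_floored <- n_floored + sum(PA < .dh_floor)
    ll[pos] <- log(pmax(PA, .dh_floor)) +
      stats::dnorm(r, log = TRUE) - log(sigma)
    if (params$variant == "exponential") ll[pos] <- ll[pos] - log(y[pos])
  }
  out <- if (by_observation) ll else sum(ll)
  attr(out, "n_floored") <- n_floored
  out
}

#' Factorized pieces of the log-likelihood
#'
#' Splits the log-likelihood into a participation part and a
#' conditional-amount part. With `rho = 0` the model separates exactly:
#' the participation part is a Bernoulli log-likelihood for the indicator
#' `y > 0` — with success probability `Phi(z'theta) * Phi(X'beta/sigma)`
#' under the linear variant (both hurdles gate a positive outcome) and
#' plain probit `Phi(z'theta)` under the exponential variant — and the
#' amount part is the truncated-normal regression log-likelihood of the
#' positive amounts (normal regression of `log y` for the exponential
#' variant). Their sum equals [dh_loglik()] exactly when `rho = 0`.
#'
#' @inheritParams dh_loglik
#' @return list with components `participation`, `amount` and `total`.
#' @export
dh_loglik_parts <- function(params, dm) {
  check_params_design(params, dm)
  if (abs(params$rho) > 0)
    warning("factorization is exact only at rho = 0", call. = FALSE)
  y <- dm$y
  idx <- dh_index(params, dm)
  pos <- y > 0
  sigma <- params$sigma
  if (params$variant == "linear") {
    p1 <- stats::pnorm(idx$q) * stats::pnorm(idx$m / sigma)
    r <- (y[pos] - idx$m[pos]) / sigma
    amount <- sum(stats::dnorm(r, log = TRUE) - log(sigma) -
                    stats::pnorm(idx$m[pos] / sigma, log.p = TRUE))
  } else {
    p1 <- stats::pnorm(idx$q)
    r <- (log(y[pos]) - idx$m[pos]) / sigma
    amount <- sum(stats::dnorm(r, log = TRUE) - log(sigma) - log(y[pos]))
  }
  participation <- sum(log(pmax(ifelse(pos, p1, 1 - p1), .dh_floor)))
  list(participation = participation, amount = amount,
       total = participation + amount)
}

#' Model probability of a zero outcome
#'
#' Closed-form probability that a household with participation index
#' `z'theta` and amount index `X'beta` records zero spending:
#' `1 - Phi2(z'theta, X'beta/sigma; rho)` for the linear variant and
#' `1 - Phi(z'theta)` for the exponential variant.
#'
#' @param params a [dh_parameters()] object.
#' @param q,m numeric vectors of participation and amount indices
#'   (`z'theta` and `X'beta`).
#' @return vector of zero probabilities.
#' @export
dh_zero_prob <- function(params, q, m) {
  if (params$variant == "linear")
    1 - pbnorm2(q, m / params$sigma, params$rho)
  else
    stats::pnorm(q, lower.tail = FALSE)
}

#' Density of a positive outcome
#'
#' The per-observation likelihood contribution of a positive outcome
#' `y`, as a density in `y`, for given covariate indices. Together with
#' [dh_zero_prob()] this integrates to one:
#' `dh_zero_prob(...) + integral of dh_density over (0, Inf) = 1`.
#'
#' @inheritParams dh_zero_prob
#' @param y vector of positive outcome values.
#' @param q,m scalar participation and amount indices.
#' @return vector of density values at `y`.
#' @export
dh_density <- function(y, params, q, m) {
  if (any(y <= 0)) stop_input("'y' must be strictly positive")
  sigma <- params$sigma
  rho <- params$rho
  s <- sqrt(1 - rho^2)
  ystar <- if (params$variant == "linear") y else log(y)
  r <- (ystar - m) / sigma
  dens <- stats::pnorm((q + rho * r) / s) * stats::dnorm(r) / sigma
  if (params$variant == "exponential") dens <- dens / y
  dens
}

# ---- parameter packing and analytic score -------------------------------
# The optimizer works on the unconstrained vector
#   par = (theta, beta, log sigma, atanh rho)
# with atanh rho dropped when rho is held at zero.

pack_par <- function(params, rho_free) {
  p <- c(params$theta, params$beta, log(params$sigma))
  if (rho_free) p <- c(p, atanh(params$rho))
  p
}

unpack_par <- function(par, kz, kx, rho_free, variant,
                       zn = NULL, xn = NULL) {
  theta <- par[seq_len(kz)]
  beta <- par[kz + seq_len(kx)]
  # exp() under/overflows at extreme trial points during line searches
  sigma <- min(max(exp(par[kz + kx + 1]), 1e-12), 1e12)
  # tanh saturates in double precision; keep rho strictly inside (-1, 1)
  rho <- if (rho_free) max(-1 + 1e-12, min(1 - 1e-12, tanh(par[kz + kx + 2]))) else 0
  if (!is.null(zn)) names(theta) <- zn
  if (!is.null(xn)) names(beta) <- xn
  dh_parameters(theta, beta, sigma, rho, variant)
}

# Negative log-likelihood and its analytic gradient on the unconstrained
# scale. Gradient identities (linear variant; exponential analogous with
# ystar = log y and no beta/sigma/rho terms in the zero part):
#   zero obs, P0 = 1 - Phi2(q, k; rho), k = m/sigma:
#     dPhi2/dq = phi(q) Phi((k - rho q)/s),  dPhi2/dk = phi(k) Phi((q - rho k)/s)
#     dPhi2/drho = binormal density at (q, k)
#   positive obs, A = (q + rho r)/s, lambda = phi(A)/Phi(A):
#     d/dtheta = lambda z / s
#     d/dbeta  = (X/sigma) (r - lambda rho / s)
#     d/dlogsigma = r^2 - 1 - lambda rho r / s
#     d/drho   = lambda (r + rho q) / s^3
dh_negll_grad <- function(par, dm, kz, kx, rho_free, variant) {
  if (any(!is.finite(par)))
    return(numeric(kz + kx + 1 + as.integer(rho_free)))
  theta <- par[seq_len(kz)]
  beta <- par[kz + seq_len(kx)]
  sigma <- exp(par[kz + kx + 1])
  a <- if (rho_free) par[kz + kx + 2] else 0
  rho <- tanh(a)
  s <- sqrt(1 - rho^2)
  y <- dm$y
  q <- drop(dm$z %*% theta)
  m <- drop(dm$X %*% beta)
  pos <- y > 0
  g_theta <- numeric(kz)
  g_beta <- numeric(kx)
  g_lsig <- 0
  g_rho <- 0
  if (any(!pos)) {
    q0 <- q[!pos]
    if (variant == "linear") {
      k0 <- m[!pos] / sigma
      P0 <- pmax(1 - pbnorm2(q0, k0, rho), .dh_floor)
      dq <- stats::dnorm(q0) * stats::pnorm((k0 - rho * q0) / s)
      dk <- stats::dnorm(k0) * stats::pnorm((q0 - rho * k0) / s)
      drho <- exp(-(q0^2 - 2 * rho * q0 * k0 + k0^2) / (2 * s^2)) / (2 * pi * s)
      w <- 1 / P0
      g_theta <- g_theta - drop(crossprod(dm$z[!pos, , drop = FALSE], dq * w))
      g_beta <- g_beta - drop(crossprod(dm$X[!pos, , drop = FALSE], dk * w)) / sigma
      g_lsig <- g_lsig + sum(dk * k0 * w)       # d(m/sigma)/dlogsigma = -k0
      g_rho <- g_rho - sum(drho * w)
    } else {
      lam0 <- stats::dnorm(q0) / pmax(stats::pnorm(-q0), .dh_floor)
      g_theta <- g_theta - drop(crossprod(dm$z[!pos, , drop = FALSE], lam0))
    }
  }
  if (any(pos)) {
    ystar <- if (variant == "linear") y[pos] else log(y[pos])
    qp <- q[pos]
    r <- (ystar - m[pos]) / sigma
    A <- (qp + rho * r) / s
    lam <- exp(stats::dnorm(A, log = TRUE) - stats::pnorm(A, log.p = TRUE))
    g_theta <- g_theta + drop(crossprod(dm$z[pos, , drop = FALSE], lam / s))
    g_beta <- g_beta +
      drop(crossprod(dm$X[pos, , drop = FALSE], (r - lam * rho / s))) / sigma
    g_lsig <- g_lsig + sum(r^2 - 1 - lam * rho * r / s)
    g_rho <- g_rho + sum(lam * (r + rho * qp) / s^3)
  }
  g <- c(g_theta, g_beta, g_lsig)
  if (rho_free) g <- c(g, g_rho * (1 - rho^2))  # chain rule for atanh
  g[!is.finite(g)] <- 0
  -g
}

dh_negll <- function(par, dm, kz, kx, rho_free, variant) {
  if (any(!is.finite(par))) return(1e10)
  params <- unpack_par(par, kz, kx, rho_free, variant)
  val <- -as.numeric(dh_loglik(params, dm))
  if (!is.finite(val)) 1e10 else val
}
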