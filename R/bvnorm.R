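#' Standard bivariate normal CDF
#'
#' Computes \eqn{\Phi_2(h, k; \rho) = P(X \le h, Y \le k)} for a pair of
#' standard normal variables with correlation \eqn{\rho}, vectorized over
#' `h` and `k`. This probability is the backbone of the dependent
#' double-hurdle likelihood: under the linear variant the probability of
#' observing a zero outcome is \eqn{1 - \Phi_2(z\theta, X\beta/\sigma; \rho)}.
#'
#' The implementation follows Genz's hybrid algorithm (Drezner &
#' Wesolowsky's transformed integral with Gauss-Legendre quadrature for
#' moderate correlations, and the asymptotic-expansion form for
#' \eqn{|\rho| > 0.925}), which attains close to double-precision accuracy
#' (absolute error well below 1e-10, the documented contract).
#'
#' @param h,k numeric vectors of upper integration limits (recycled to a
#'   common length).
#' @param rho scalar correlation in \[-1, 1\].
#' @return numeric vector of probabilities.
#' @examples
#' pbnorm2(0, 0, 0)     # 0.25
#' pbnorm2(0, 0, 0.5)   # 1/4 + asin(0.5)/(2*pi) = 1/3
#' @export
pbnorm2 <- function(h, k, rho) {
  if (length(rho) != 1 || !is.finite(rho) || abs(rho) > 1)
    stop_input("'rho' must be a single finite value in [-1, 1]")
  n <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  if (rho == 0) return(stats::pnorm(h) * stats::pnorm(k))
  if (rho == 1) return(stats::pnorm(pmin(h, k)))
  if (rho == -1) return(pmax(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  out <- numeric(n)
  fin <- is.finite(h) & is.finite(k)
  # Infinite limits reduce to univariate margins.
  out[h == -Inf | k == -Inf] <- 0
  hi <- !fin & h == Inf & k > -Inf
  ki <- !fin & k == Inf & h > -Inf
  out[hi] <- stats::pnorm(k[hi])
  out[ki] <- stats::pnorm(h[ki])
  out[hi & ki] <- 1
  if (any(fin)) out[fin] <- bvnd_upper(-h[fin], -k[fin], rho)
  out
}

# Gauss-Legendre nodes/weights on [-1, 1] (half set; used with both signs).
.gl_nodes <- list(
  x6  = c(0.9324695142031521, 0.6612093864662645, 0.2386191860831969),
  w6  = c(0.1713244923791704, 0.3607615730481386, 0.4679139345726910),
  x12 = c(0.9815606342467192, 0.9041172563704749, 0.7699026741943047,
          0.5873179542866175, 0.3678314989981802, 0.1252334085114689),
  w12 = c(0.04717533638651183, 0.1069393259953184, 0.1600783285433462,
          0.2031674267230659, 0.2334925365383548, 0.2491470458134028),
  x20 = c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
          0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
          0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
          0.07652652113349733),
  w20 = c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
          0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
          0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
          0.1527533871307259))

# P(X > dh, Y > dk) for standard bivariate normal with correlation r,
# vectorized over (dh, dk); |r| < 1 and finite limits assumed.
bvnd_upper <- function(dh, dk, r) {
  if (abs(r) < 0.3) {
    x <- .gl_nodes$x6;  w <- .gl_nodes$w6
  } else if (abs(r) < 0.75) {
    x <- .gl_nodes$x12; w <- .gl_nodes$w12
  } else {
    x <- .gl_nodes$x20; w <- .gl_nodes$w20
  }
  h <- dh
  k <- dk
  hk <- h * k
  bvn <- numeric(length(h))
  if (abs(r) < 0.925) {
    hs <- (h * h + k * k) / 2
    asr <- asin(r)
    for (i in seq_along(x)) {
      for (is in c(-1, 1)) {
        sn <- sin(asr * (is * x[i] + 1) / 2)
        bvn <- bvn + w[i] * exp((sn * hk - hs) / (1 - sn * sn))
      }
    }
    bvn <- bvn * asr / (4 * pi) + stats::pnorm(-h) * stats::pnorm(-k)
  } else {
    if (r < 0) {
      k <- -k
      hk <- -hk
    }
    as_ <- (1 - r) * (1 + r)
    a <- sqrt(as_)
    bs <- (h - k)^2
    cc <- (4 - hk) / 8
    d <- (12 - hk) / 16
    asr <- -(bs / as_ + hk) / 2
    bvn <- ifelse(asr > -100,
                  a * exp(asr) * (1 - cc * (bs - as_) * (1 - d * bs / 5) / 3 +
                                    cc * d * as_ * as_ / 5),
                  0)
    b <- sqrt(bs)
    tail_ok <- -hk < 100
    sp <- sqrt(2 * pi) * stats::pnorm(-b / a)
    bvn <- bvn - ifelse(tail_ok,
                        exp(-hk / 2) * sp * b * (1 - cc * bs * (1 - d * bs / 5) / 3),
                        0)
    a2 <- a / 2
    for (i in seq_along(x)) {
      for (is in c(-1, 1)) {
        xs <- (a2 * (is * x[i] + 1))^2
        rs <- sqrt(1 - xs)
        asr1 <- -(bs / xs + hk) / 2
        add <- ifelse(asr1 > -100,
                      a2 * w[i] * exp(asr1) *
                        (exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs -
                           (1 + cc * xs * (1 + d * xs))),
                      0)
        bvn <- bvn + add
      }
    }
    bvn <- -bvn / (2 * pi)
    if (r > 0) {
      bvn <- bvn + stats::pnorm(-pmax(h, k))
    } else {
      bvn <- -bvn
      adj <- k > h
      bvn[adj] <- bvn[adj] + stats::pnorm(k[adj]) - stats::pnorm(h[adj])
    }
  }
  pmin(1, pmax(0, bvn))
}
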