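# Maximum-likelihood fitting: probit and truncated-normal starting fits,
# then quasi-Newton maximization of the joint likelihood on the
# unconstrained scale (theta, beta, log sigma, atanh rho), a short Newton
# polish to drive the score to zero, and observed-information standard
# errors with a delta-method back-transform for sigma and rho.

#' Probit participation fit
#'
#' Standard probit MLE of a binary participation indicator on the
#' participation design matrix, via [stats::glm.fit()]. Used to start the
#' joint optimization. On (quasi-)perfect separation a warning is issued
#' and a ridge-penalized refit is returned instead, so starting values
#' stay finite.
#'
#' @param z numeric design matrix (including any intercept column).
#' @param d binary 0/1 vector with both classes present.
#' @return list with `theta` (coefficients), `loglik` and `separation`
#'   flag.
#' @export
probit_fit <- function(z, d) {
  z <- as.matrix(z)
  d <- as.numeric(d)
  if (!all(d %in% c(0, 1))) stop_input("'d' must be a binary 0/1 vector")
  if (length(unique(d)) < 2)
    stop_input("'d' must contain both zeros and ones")
  sep <- FALSE
  fit <- withCallingHandlers(
    suppressWarnings(stats::glm.fit(z, d, family = stats::binomial("probit"))),
    error = function(e) e)
  eta <- drop(z %*% fit$coefficients)
  if (!fit$converged || any(abs(eta) > 7.5)) {
    sep <- TRUE
    warning("possible separation in probit fit; using penalized estimates",
            call. = FALSE)
    lambda <- 1e-3 * nrow(z)
    negll <- function(b) {
      e <- drop(z %*% b)
      -sum(ifelse(d == 1, stats::pnorm(e, log.p = TRUE),
                  stats::pnorm(-e, log.p = TRUE))) + lambda * sum(b^2) / 2
    }
    opt <- stats::optim(rep(0, ncol(z)), negll, method = "BFGS",
                        control = list(maxit = 500))
    fit$coefficients <- opt$par
  }
  theta <- fit$coefficients
  names(theta) <- colnames(z)
  eta <- drop(z %*% theta)
  ll <- sum(ifelse(d == 1, stats::pnorm(eta, log.p = TRUE),
                   stats::pnorm(-eta, log.p = TRUE)))
  list(theta = theta, loglik = ll, separation = sep)
}

#' Truncated-normal regression fit
#'
#' MLE of a linear regression whose outcome is normal but observed only
#' when positive (truncation at zero): density
#' `phi((y - X beta)/sigma) / (sigma * Phi(X beta / sigma))`. Used for
#' second-hurdle starting values and as a standalone fit for positive
#' spenders.
#'
#' @param X_pos design matrix of the positive observations.
#' @param y_pos strictly positive outcome vector.
#' @return list with `beta`, `sigma`, `loglik`, `vcov`
#'   (observed-information covariance on the natural scale) and
#'   `converged`.
#' @export
trunc_reg_fit <- function(X_pos, y_pos) {
  X_pos <- as.matrix(X_pos)
  y_pos <- as.numeric(y_pos)
  if (any(y_pos <= 0)) stop_input("'y_pos' must be strictly positive")
  if (nrow(X_pos) != length(y_pos)) stop_input("row mismatch between X and y")
  k <- ncol(X_pos)
  ls <- stats::lm.fit(X_pos, y_pos)
  b0 <- ls$coefficients
  b0[is.na(b0)] <- 0  # columns collinear (or constant) within the subsample
  start <- c(b0, log(max(sqrt(mean(ls$residuals^2)), 1e-6)))
  negll <- function(p) {
    beta <- p[seq_len(k)]
    sigma <- exp(p[k + 1])
    m <- drop(X_pos %*% beta)
    r <- (y_pos - m) / sigma
    -sum(stats::dnorm(r, log = TRUE) - log(sigma) -
           stats::pnorm(m / sigma, log.p = TRUE))
  }
  grad <- function(p) {
    beta <- p[seq_len(k)]
    sigma <- exp(p[k + 1])
    m <- drop(X_pos %*% beta)
    r <- (y_pos - m) / sigma
    k0 <- m / sigma
    lam <- exp(stats::dnorm(k0, log = TRUE) - stats::pnorm(k0, log.p = TRUE))
    gb <- drop(crossprod(X_pos, r - lam)) / sigma
    gs <- sum(r^2 - 1 + lam * k0)
    -c(gb, gs)
  }
  opt <- stats::optim(start, negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  par <- newton_polish(opt$par, negll, grad, tol = 1e-8)
  beta <- par[seq_len(k)]
  names(beta) <- colnames(X_pos)
  sigma <- exp(par[k + 1])
  # observed information; delta method for sigma = exp(log sigma)
  H <- num_jacobian(grad, par)
  H <- (H + t(H)) / 2
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k + 1, k + 1))
  J <- diag(k + 1)
  J[k + 1, k + 1] <- sigma
  vc <- J %*% vc %*% t(J)
  dimnames(vc) <- list(c(names(beta), "sigma"), c(names(beta), "sigma"))
  list(beta = beta, sigma = sigma, loglik = -negll(par), vcov = vc,
       converged = max(abs(grad(par))) < 1e-6)
}

# Newton refinement of the BFGS optimum. Near the maximum the likelihood
# itself is flat to double rounding, so steps are accepted on a reduction
# of the score max-norm (with a function-decrease fallback), which lets
# quadratic convergence drive the score to ~0 even when the objective can
# no longer discriminate.
newton_polish <- function(par, negll, grad, max_steps = 12, tol = 1e-8,
                          project = identity) {
  g <- grad(par)
  for (i in seq_len(max_steps)) {
    if (!all(is.finite(g)) || max(abs(g)) < tol) break
    H <- num_jacobian(grad, par)
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      step <- g / max(1, max(abs(g)))
    gn0 <- max(abs(g))
    f0 <- negll(par)
    lambda <- 1
    accepted <- FALSE
    while (lambda >= 1e-4) {
      cand <- project(par - lambda * step)
      fc <- negll(cand)
      if (is.finite(fc)) {
        gc_ <- grad(cand)
        if (all(is.finite(gc_)) &&
            (max(abs(gc_)) < gn0 || fc < f0 - 1e-10)) {
          par <- cand
          g <- gc_
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!accepted) break
  }
  par
}

#' Fit the double-hurdle model by maximum likelihood
#'
#' Maximizes the dependent double-hurdle log-likelihood over the
#' unconstrained parameterization (theta, beta, log sigma, atanh rho),
#' started from a probit participation fit and a truncated-normal (or
#' log-scale linear) amount fit with rho = 0. Standard errors come from
#' the inverse observed information (numerical Jacobian of the analytic
#' score) with a delta-method back-transform for sigma and rho. The
#' result also carries an intercept-only null fit of the same variant
#' and rho mode, the likelihood-ratio statistic, McFadden pseudo
#' R-squared and (when rho is free) the Wald test of error independence.
#'
#' @param dm a `dh_design` with at least one zero and one positive
#'   outcome and full-column-rank matrices.
#' @param variant outcome-equation form, `"linear"` (default) or
#'   `"exponential"`.
#' @param rho_mode `"free"` to estimate the error correlation,
#'   `"fixed_zero"` for Cragg's independent model.
#' @param start optional [dh_parameters()] overriding the default
#'   starting values.
#' @param fit_null logical; fit the intercept-only null model for the
#'   LR test and pseudo R-squared (default `TRUE`).
#' @param control list; `maxit` (default 500), `reltol` (default 1e-10)
#'   and `grad_tol` (default 1e-6, convergence criterion on the maximum
#'   absolute score component).
#' @return an object of class `dh_fit`; see the package vignette.
#' @examples
#' hh <- simulate_households(synthetic_config(400, seed = 3,
#'                                            outcome_variant = "exponential"))
#' fit <- fit_dh(encode_design(hh), variant = "exponential")
#' fit$loglik > fit$loglik_null
#' @export
fit_dh <- function(dm, variant = c("linear", "exponential"),
                   rho_mode = c("free", "fixed_zero"),
                   start = NULL, fit_null = TRUE, control = list()) {
  variant <- match.arg(variant)
  rho_mode <- match.arg(rho_mode)
  if (!inherits(dm, "dh_design")) stop_input("'dm' must be a dh_design object")
  if (is.null(dm$y)) stop_input("design has no outcome vector 'y'")
  y <- dm$y
  pos <- y > 0
  if (all(pos))
    stop_input("all outcomes are positive: the participation hurdle is ",
               "uninformative; fit a truncated regression instead (trunc_reg_fit)")
  if (!any(pos))
    stop_input("all outcomes are zero: the amount hurdle is uninformative; ",
               "fit a probit instead (probit_fit)")
  for (blk in c("z", "X")) {
    M <- dm[[blk]]
    if (qr(M)$rank < ncol(M))
      stop_input("design matrix '", blk, "' is rank deficient")
  }
  ctrl <- list(maxit = 500, reltol = 1e-10, grad_tol = 1e-6)
  ctrl[names(control)] <- control
  kz <- ncol(dm$z)
  kx <- ncol(dm$X)
  rho_free <- rho_mode == "free"

  # Fit on unit-SD rescaled columns (a pure reparameterization) so that
  # raw-currency covariates do not ruin the optimizer's conditioning;
  # estimates and covariance are transformed back afterwards.
  col_scale <- function(M) apply(M, 2, function(cl) {
    s <- stats::sd(cl)
    if (!is.finite(s) || s < 1e-12) 1 else s
  })
  sc_z <- col_scale(dm$z)
  sc_x <- col_scale(dm$X)
  dm_raw <- dm
  dm <- design_matrices(sweep(dm$z, 2, sc_z, "/"),
                        sweep(dm$X, 2, sc_x, "/"), y)

  if (is.null(start)) {
    pr <- probit_fit(dm$z, as.numeric(pos))
    ystar <- if (variant == "linear") y[pos] else log(y[pos])
    Xp <- dm$X[pos, , drop = FALSE]
    if (variant == "linear") {
      tr <- trunc_reg_fit(Xp, ystar)
      beta0 <- tr$beta; sigma0 <- tr$sigma
    } else {
      ls <- stats::lm.fit(Xp, ystar)
      beta0 <- ls$coefficients
      sigma0 <- sqrt(mean(ls$residuals^2))
    }
    beta0[is.na(beta0)] <- 0
    theta0 <- pr$theta
    theta0[is.na(theta0)] <- 0
    start <- dh_parameters(theta0, beta0, max(sigma0, 1e-8), 0, variant)
  } else {
    if (!inherits(start, "dh_parameters")) stop_input("'start' must be dh_parameters")
    if (start$variant != variant) stop_input("'start' variant mismatch")
    start <- dh_parameters(start$theta * sc_z, start$beta * sc_x,
                           start$sigma, start$rho, variant)
  }

  negll <- function(p) dh_negll(p, dm, kz, kx, rho_free, variant)
  grad <- function(p) dh_negll_grad(p, dm, kz, kx, rho_free, variant)

  # Stage 1: always solve the independent (rho = 0) problem first — it is
  # well conditioned and its solution is an excellent warm start.
  negll0 <- function(p) dh_negll(p, dm, kz, kx, FALSE, variant)
  grad0 <- function(p) dh_negll_grad(p, dm, kz, kx, FALSE, variant)
  par00 <- pack_par(dh_parameters(start$theta, start$beta, start$sigma,
                                  0, variant), FALSE)
  opt0 <- stats::optim(par00, negll0, grad0, method = "BFGS",
                       control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
  par_fixed <- newton_polish(opt0$par, negll0, grad0, tol = ctrl$grad_tol / 10)
  n_iter <- unname(opt0$counts["function"])

  if (!rho_free) {
    par <- par_fixed
  } else {
    # Stage 2: release rho from the stage-1 optimum, with box bounds on
    # atanh(rho) so a weakly identified correlation cannot run off into
    # the flat clamped region near the boundary (|rho| <= tanh(4)).
    pstart <- c(par_fixed, atanh(start$rho))
    bound <- c(rep(Inf, kz + kx + 1), 4)
    proj <- function(p) {
      p[kz + kx + 2] <- max(-4, min(4, p[kz + kx + 2]))
      p
    }
    opt <- stats::optim(pstart, negll, grad, method = "L-BFGS-B",
                        lower = -bound, upper = bound,
                        control = list(maxit = ctrl$maxit, factr = 10))
    par <- newton_polish(opt$par, negll, grad, tol = ctrl$grad_tol / 10,
                         project = proj)
    n_iter <- n_iter + unname(opt$counts["function"])
    # restart with a fresh Hessian approximation if the score criterion
    # is still unmet (flat ridges in small, dummy-heavy designs)
    for (round in 1:2) {
      if (max(abs(grad(par))) < ctrl$grad_tol) break
      optr <- stats::optim(proj(par), negll, grad, method = "L-BFGS-B",
                           lower = -bound, upper = bound,
                           control = list(maxit = ctrl$maxit, factr = 10))
      par <- newton_polish(optr$par, negll, grad, tol = ctrl$grad_tol / 10,
                           project = proj)
      n_iter <- n_iter + unname(optr$counts["function"])
    }
  }
  g <- grad(par)
  converged <- max(abs(g)) < ctrl$grad_tol
  at_boundary <- rho_free && abs(tanh(par[kz + kx + 2])) > 0.999
  if (at_boundary) {
    converged <- FALSE
    warning("estimated error correlation is at the boundary (|rho| > 0.999); ",
            "the dependence parameter is weakly identified in this sample",
            call. = FALSE)
  } else if (!converged) {
    warning("double-hurdle fit did not meet the score criterion (max |score| = ",
            format(max(abs(g)), digits = 3), ")", call. = FALSE)
  }

  params_s <- unpack_par(par, kz, kx, rho_free, variant,
                         colnames(dm$z), colnames(dm$X))
  params <- dh_parameters(params_s$theta / sc_z, params_s$beta / sc_x,
                          params_s$sigma, params_s$rho, variant)
  ll <- dh_loglik(params_s, dm)
  n_floored <- attr(ll, "n_floored")
  if (n_floored > 0)
    warning(n_floored, " likelihood term(s) floored at 1e-300", call. = FALSE)

  # Observed information on the unconstrained scale, then delta method
  # back to (theta, beta, sigma, rho).
  H <- num_jacobian(grad, par)
  H <- (H + t(H)) / 2
  vcov_t <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vcov_t)) {
    vcov_t <- tryCatch(MASS::ginv(H), error = function(e) NULL)
    if (!is.null(vcov_t))
      warning("observed information is ill-conditioned; ",
              "standard errors use a generalized inverse", call. = FALSE)
  }
  npar <- length(par)
  nat_names <- c(colnames(dm$z), colnames(dm$X), "sigma",
                 if (rho_free) "rho")
  if (is.null(vcov_t)) {
    vcov <- matrix(NA_real_, npar, npar)
    warning("observed information is singular; standard errors unavailable",
            call. = FALSE)
  } else {
    J <- diag(npar)
    J[kz + kx + 1, kz + kx + 1] <- params$sigma          # d sigma / d log sigma
    if (rho_free) J[npar, npar] <- 1 - params$rho^2      # d rho / d atanh rho
    vcov <- J %*% vcov_t %*% t(J)
    # undo the column rescaling
    Tm <- diag(c(1 / sc_z, 1 / sc_x, 1, if (rho_free) 1))
    vcov <- Tm %*% vcov %*% Tm
  }
  dimnames(vcov) <- list(nat_names, nat_names)

  null_fit <- NULL
  ll0 <- NA_real_
  if (fit_null) {
    dm0 <- design_matrices(matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")),
                           matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")),
                           y)
    null_fit <- fit_dh(dm0, variant = variant, rho_mode = rho_mode,
                       fit_null = FALSE)
    ll0 <- null_fit$loglik
  }
  lr_chi2 <- if (fit_null) 2 * (as.numeric(ll) - ll0) else NA_real_
  lr_df <- if (fit_null) (kz + kx) - 2 else NA_integer_

  fit <- structure(list(
    params = params,
    vcov = vcov,
    loglik = as.numeric(ll),
    loglik_null = ll0,
    lr_chi2 = lr_chi2,
    lr_df = lr_df,
    pseudo_r2 = if (fit_null && ll0 < 0) 1 - as.numeric(ll) / ll0 else NA_real_,
    rho_mode = rho_mode,
    converged = converged,
    n_iter = n_iter,
    n_obs = length(y),
    n_zero = sum(!pos),
    n_floored = n_floored,
    score_norm = max(abs(g)),
    null_fit = null_fit), class = "dh_fit")
  if (rho_free) {
    fit$wald_rho <- tryCatch(wald_rho_test(fit), error = function(e) {
      warning("Wald test of rho unavailable: ", conditionMessage(e),
              call. = FALSE)
      list(statistic = NA_real_, df = 1L, p_value = NA_real_)
    })
  }
  fit
}

#' @export
coef.dh_fit <- function(object, ...) {
  c(object$params$theta, object$params$beta,
    sigma = object$params$sigma,
    if (object$rho_mode == "free") c(rho = object$params$rho))
}

#' @export
vcov.dh_fit <- function(object, ...) object$vcov

#' @export
logLik.dh_fit <- function(object, ...) {
  structure(object$loglik, df = nrow(object$vcov), class = "logLik")
}

dh_se <- function(fit) sqrt(pmax(diag(fit$vcov), 0))

#' @export
print.dh_fit <- function(x, ...) {
  cat("Double-hurdle model (", x$params$variant, " variant, rho ",
      if (x$rho_mode == "free") "free" else "fixed at 0", ")\n", sep = "")
  cat("  n =", x$n_obs, " (", x$n_zero, "zeros )\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8), "\n")
  if (is.finite(x$loglik_null)) {
    cat("  LR chi2 =", format(x$lr_chi2, digits = 6),
        "on", x$lr_df, "df; pseudo R2 =", format(x$pseudo_r2, digits = 4), "\n")
  }
  if (!is.null(x$wald_rho))
    cat("  Wald test of rho = 0: chi2(1) =",
        format(x$wald_rho$statistic, digits = 5),
        ", p =", format.pval(x$wald_rho$p_value, digits = 4), "\n")
  cat("  sigma =", format(x$params$sigma, digits = 5),
      " rho =", format(x$params$rho, digits = 5), "\n")
  cat("  converged:", x$converged, "\n")
  invisible(x)
}
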