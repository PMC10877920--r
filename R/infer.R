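# Inference on a fitted double-hurdle model: Wald test of independent
# errors, likelihood-ratio goodness of fit, McFadden pseudo R-squared,
# and model-implied predictions.

#' Wald test of independent errors
#'
#' Tests the null hypothesis that the latent errors of the participation
#' and expenditure equations are uncorrelated (rho = 0), using the squared
#' ratio of the estimate to its standard error, referred to chi-squared
#' with one degree of freedom. Rejection indicates the dependent
#' double-hurdle model is needed rather than Cragg's independent form.
#'
#' @param fit a `dh_fit` with `rho_mode = "free"` and a valid covariance.
#' @return list with `statistic`, `df = 1` and `p_value`.
#' @examples
#' # statistic = (rho / se)^2: rho = 0.2, se = 0.1 gives 4, p ~ 0.0455
#' @export
wald_rho_test <- function(fit) {
  if (!inherits(fit, "dh_fit")) stop_input("'fit' must be a dh_fit object")
  if (fit$rho_mode != "free")
    stop_input("Wald test of rho requires a fit with rho_mode = 'free'")
  if (!"rho" %in% rownames(fit$vcov) || !is.finite(fit$vcov["rho", "rho"]))
    stop_input("fit has no valid covariance entry for rho")
  se_rho <- sqrt(fit$vcov["rho", "rho"])
  stat <- if (fit$params$rho == 0) 0 else (fit$params$rho / se_rho)^2
  list(statistic = as.numeric(stat), df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Likelihood-ratio test between nested double-hurdle fits
#'
#' Goodness-of-fit test comparing a full model with a nested null model
#' (by default the intercept-only fit stored on the full fit):
#' `chi2 = 2 * (loglik_full - loglik_null)` on the difference in
#' parameter counts.
#'
#' @param fit_full a `dh_fit`.
#' @param fit_null a nested `dh_fit` on the same data and variant;
#'   defaults to the intercept-only null fitted alongside `fit_full`.
#' @return list with `chi2`, `df` and `p`.
#' @export
lr_test <- function(fit_full, fit_null = fit_full$null_fit) {
  if (!inherits(fit_full, "dh_fit")) stop_input("'fit_full' must be a dh_fit")
  if (is.null(fit_null))
    stop_input("no null fit available; refit with fit_null = TRUE or supply one")
  if (!inherits(fit_null, "dh_fit")) stop_input("'fit_null' must be a dh_fit")
  if (fit_full$n_obs != fit_null$n_obs || fit_full$n_zero != fit_null$n_zero)
    stop_input("fits were not computed on the same data")
  if (fit_full$params$variant != fit_null$params$variant)
    stop_input("fits use different outcome variants")
  df <- nrow(fit_full$vcov) - nrow(fit_null$vcov)
  if (df < 0) stop_input("'fit_null' has more parameters than 'fit_full'")
  chi2 <- 2 * (fit_full$loglik - fit_null$loglik)
  if (chi2 < 0 && chi2 > -1e-8) chi2 <- 0
  if (chi2 < 0)
    stop_input("null log-likelihood exceeds the full model's: fits are not nested")
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = max(df, 1), lower.tail = FALSE))
}

#' McFadden pseudo R-squared
#'
#' `1 - loglik / loglik_null`, with the intercept-only model of the same
#' variant and rho mode as the null.
#'
#' @param fit a `dh_fit` carrying a null fit.
#' @return scalar pseudo R-squared.
#' @export
pseudo_r2 <- function(fit) {
  if (!inherits(fit, "dh_fit")) stop_input("'fit' must be a dh_fit")
  if (!is.finite(fit$loglik_null))
    stop_input("fit carries no null log-likelihood")
  if (fit$loglik_null >= 0)
    stop_input("pseudo R-squared requires a negative null log-likelihood")
  1 - fit$loglik / fit$loglik_null
}

#' Predicted participation probability
#'
#' Probability that a household passes the first (spending-decision)
#' hurdle, `Phi(z' theta)`; monotone increasing in the participation
#' index.
#'
#' @param params a [dh_parameters()] object.
#' @param z_row numeric vector (one household) or matrix (one row per
#'   household) of participation covariates.
#' @return vector of probabilities in \[0, 1\].
#' @export
predict_participation <- function(params, z_row) {
  z <- if (is.matrix(z_row)) z_row else matrix(z_row, nrow = 1)
  if (ncol(z) != length(params$theta))
    stop_input("'z_row' has ", ncol(z), " columns but theta has length ",
               length(params$theta))
  stats::pnorm(drop(z %*% params$theta))
}

#' Model-implied expected spending
#'
#' Unconditional expectation of the observed outcome (zeros included)
#' for a household with the given covariate rows. Computed by adaptive
#' quadrature over the latent amount error in general; when `rho = 0`
#' the exact closed form is used
#' (linear variant: `Phi(q) * [m * Phi(m/sigma) + sigma * phi(m/sigma)]`;
#' exponential: `Phi(q) * exp(m + sigma^2/2)`).
#'
#' @param params a [dh_parameters()] object.
#' @param z_row,X_row covariate vectors (one household) or matrices
#'   (row-matched).
#' @return vector of non-negative expected outcomes.
#' @export
predict_expected_y <- function(params, z_row, X_row) {
  z <- if (is.matrix(z_row)) z_row else matrix(z_row, nrow = 1)
  X <- if (is.matrix(X_row)) X_row else matrix(X_row, nrow = 1)
  if (nrow(z) != nrow(X)) stop_input("'z_row' and 'X_row' row counts differ")
  if (ncol(z) != length(params$theta) || ncol(X) != length(params$beta))
    stop_input("covariate dimensions do not match the parameter vectors")
  q <- drop(z %*% params$theta)
  m <- drop(X %*% params$beta)
  sigma <- params$sigma
  rho <- params$rho
  s <- sqrt(1 - rho^2)
  n <- length(q)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (rho == 0) {
      out[i] <- if (params$variant == "linear")
        stats::pnorm(q[i]) * (m[i] * stats::pnorm(m[i] / sigma) +
                                sigma * stats::dnorm(m[i] / sigma))
      else
        stats::pnorm(q[i]) * exp(m[i] + sigma^2 / 2)
    } else {
      # E[y 1{both hurdles}] = int (amount) phi(u) Phi((q + rho u)/s) du
      # over the region where the amount is positive (all u for the
      # exponential variant).
      integrand <- if (params$variant == "linear") {
        function(u) (m[i] + sigma * u) * stats::dnorm(u) *
          stats::pnorm((q[i] + rho * u) / s)
      } else {
        function(u) exp(m[i] + sigma * u) * stats::dnorm(u) *
          stats::pnorm((q[i] + rho * u) / s)
      }
      lower <- if (params$variant == "linear") -m[i] / sigma else -Inf
      out[i] <- stats::integrate(integrand, lower, Inf,
                                 rel.tol = 1e-9, abs.tol = 1e-12)$value
    }
  }
  pmax(out, 0)
}
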