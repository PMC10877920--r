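#' Double-hurdle parameter set
#'
#' Bundles every parameter of the double-hurdle model: the participation
#' (probit) coefficients `theta`, the expenditure coefficients `beta`, the
#' standard deviation `sigma` of the expenditure error, the correlation
#' `rho` between the two latent errors, and the outcome-equation variant.
#'
#' Under the model, a household's decision to spend is governed by a latent
#' index \eqn{z_i\theta + \epsilon_i} with \eqn{\epsilon_i \sim N(0, 1)};
#' the desired amount is \eqn{X_i\beta + v_i} (linear variant) or
#' \eqn{\exp(X_i\beta + v_i)} (exponential variant) with
#' \eqn{v_i \sim N(0, \sigma^2)} and \eqn{cor(\epsilon_i, v_i) = \rho}.
#' A positive outcome is observed only when both hurdles are passed.
#'
#' @param theta numeric vector of participation coefficients (one per
#'   column of the participation design matrix `z`).
#' @param beta numeric vector of expenditure coefficients (one per column
#'   of the expenditure design matrix `X`).
#' @param sigma positive scalar, SD of the expenditure-equation error.
#' @param rho scalar correlation of the latent errors, in (-1, 1).
#' @param variant `"linear"` (truncated-normal amounts) or
#'   `"exponential"` (lognormal amounts).
#' @return an object of class `dh_parameters`.
#' @examples
#' dh_parameters(theta = c(0.5, -0.8), beta = c(2, 1), sigma = 1.5, rho = 0.5)
#' @export
dh_parameters <- function(theta, beta, sigma, rho = 0,
                          variant = c("linear", "exponential")) {
  variant <- match.arg(variant)
  theta <- stats::setNames(as.numeric(theta), names(theta))
  beta <- stats::setNames(as.numeric(beta), names(beta))
  if (length(theta) < 1 || length(beta) < 1 || any(!is.finite(c(theta, beta))))
    stop_input("'theta' and 'beta' must be non-empty finite numeric vectors")
  if (length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    stop_input("'sigma' must be a single positive number")
  if (length(rho) != 1 || !is.finite(rho) || abs(rho) >= 1)
    stop_input("'rho' must be a single number strictly inside (-1, 1)")
  structure(list(theta = theta, beta = beta, sigma = as.numeric(sigma),
                 rho = as.numeric(rho), variant = variant),
            class = "dh_parameters")
}

#' @export
print.dh_parameters <- function(x, ...) {
  cat("Double-hurdle parameters (", x$variant, " variant)\n", sep = "")
  cat("  theta:", format(x$theta, digits = 4), "\n")
  cat("  beta: ", format(x$beta, digits = 4), "\n")
  cat("  sigma:", format(x$sigma, digits = 4),
      " rho:", format(x$rho, digits = 4), "\n")
  invisible(x)
}

#' Design matrices for the two hurdles
#'
#' Container pairing the participation design matrix `z`, the expenditure
#' design matrix `X` and the observed non-negative outcome `y`. Usually
#' produced by [encode_design()]; this constructor is exported so that
#' hand-built matrices (e.g. intercept-only nulls) can be fitted too.
#'
#' @param z numeric matrix of participation covariates (n x k_z).
#' @param X numeric matrix of expenditure covariates (n x k_x).
#' @param y numeric outcome vector of length n, non-negative, zeros
#'   allowed; may be `NULL` for prediction-only designs.
#' @return an object of class `dh_design`.
#' @export
design_matrices <- function(z, X, y = NULL) {
  z <- as.matrix(z)
  X <- as.matrix(X)
  if (nrow(z) != nrow(X))
    stop_input("'z' and 'X' must have the same number of rows")
  if (any(!is.finite(z)) || any(!is.finite(X)))
    stop_input("design matrices must not contain non-finite entries")
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(z))
      stop_input("length of 'y' must match the design row count")
    if (any(!is.finite(y)) || any(y < 0))
      stop_input("'y' must be finite and non-negative (zeros allowed)")
  }
  if (is.null(colnames(z))) colnames(z) <- paste0("z", seq_len(ncol(z)))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(z = z, X = X, y = y,
                 column_names = list(participation = colnames(z),
                                     expenditure = colnames(X))),
            class = "dh_design")
}

check_params_design <- function(params, dm) {
  if (!inherits(params, "dh_parameters")) stop_input("'params' must be a dh_parameters object")
  if (!inherits(dm, "dh_design")) stop_input("'dm' must be a dh_design object")
  if (length(params$theta) != ncol(dm$z))
    stop_input("length(theta) = ", length(params$theta),
               " does not match ncol(z) = ", ncol(dm$z))
  if (length(params$beta) != ncol(dm$X))
    stop_input("length(beta) = ", length(params$beta),
               " does not match ncol(X) = ", ncol(dm$X))
  invisible(TRUE)
}
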