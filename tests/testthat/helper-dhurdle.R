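# Shared fixtures, built in code.

# Minimal known-truth DGP: one binary covariate in each hurdle, errors
# bivariate normal. Returns a dh_design ready for fit_dh(). Independent
# of simulate_households() so estimator tests do not lean on the
# generator under test.
simple_dgp <- function(n, theta = c(0.5, -0.8), beta = c(2, 1),
                       sigma = 1.5, rho = 0.5, seed = 1,
                       variant = c("linear", "exponential")) {
  variant <- match.arg(variant)
  set.seed(seed)
  z <- cbind("(Intercept)" = 1, zcov = stats::rbinom(n, 1, 0.5))
  X <- cbind("(Intercept)" = 1, xcov = stats::rbinom(n, 1, 0.5))
  eps <- stats::rnorm(n)
  u <- rho * eps + sqrt(1 - rho^2) * stats::rnorm(n)
  q <- drop(z %*% theta)
  m <- drop(X %*% beta)
  if (variant == "linear") {
    amt <- m + sigma * u
    y <- ifelse(q + eps > 0 & amt > 0, amt, 0)
  } else {
    y <- ifelse(q + eps > 0, exp(m + sigma * u), 0)
  }
  design_matrices(z, X, y)
}

# A tiny hand-written household table covering every enum field.
toy_households <- function() {
  data.frame(
    head_gender = c("female", "male", "male", "female", "male"),
    head_age_group = c("18-34", "35-51", "52-68", "69-85", "86+"),
    living_sector = c("urban", "rural", "urban", "rural", "urban"),
    marital_status = c("single", "divorced", "widowed", "married", "married"),
    education = c("illiterate", "primary", "secondary", "college+", "illiterate"),
    job_status = c("housekeeper", "unemployed", "employed", "employed", "employed"),
    ownership = c("free", "tenant", "owner", "owner", "owner"),
    n_children_under5 = c(0L, 1L, 0L, 0L, 2L),
    family_size_group = c("1-2", "3-5", "6+", "1-2", "3-5"),
    income = c(5000, 8000, 12000, 9000, 20000),
    insurance_cost = c(0, 120, 350, 90, 400),
    oop_pharma = c(0, 45.5, 0, 220, 12),
    stringsAsFactors = FALSE)
}

# Intercept-only parameter helper sized for the default design (22
# columns per hurdle).
full_params <- function(theta0, beta0, sigma, rho = 0,
                        variant = "linear", k = 22) {
  dh_parameters(theta = c(theta0, rep(0, k - 1)),
                beta = c(beta0, rep(0, k - 1)),
                sigma = sigma, rho = rho, variant = variant)
}
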