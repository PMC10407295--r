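# Marginal specifications and copula helpers for the synthetic survey generator.

# Published summary statistics of the UKHLS-like analysis sample: per-variable
# means/SDs for continuous measures and category proportions for categorical
# ones. These are the generator's default calibration targets.
default_marginals <- function() {
  list(
    sport  = list(type = "count", mean = 3.398, sd = 2.896, lower = 0, upper = 10),
    age    = list(type = "truncnorm", mean = 52.069, sd = 16.713, lower = 16, upper = 98),
    income = list(type = "lognormal", mean = 1978.723, sd = 1534.189),
    bmi    = list(type = "truncnorm", mean = 27.960, sd = 5.096, lower = 10, upper = Inf),
    occupation = list(
      type = "categorical",
      levels = c(
        "Large employers & higher management", "Higher professional",
        "Lower management & professional", "Intermediate",
        "Small employers & own account", "Lower supervisory & technical",
        "Semi-routine", "Routine", "Not in LM"
      ),
      # printed proportions sum to 1.001; renormalized
      prop = c(0.032, 0.044, 0.162, 0.079, 0.055, 0.044, 0.095, 0.055, 0.435) /
        sum(c(0.032, 0.044, 0.162, 0.079, 0.055, 0.044, 0.095, 0.055, 0.435))
    ),
    education = list(
      type = "categorical",
      levels = c(
        "Degree", "Other higher degree", "A-level", "GCSE",
        "Other qualification", "No qualification"
      ),
      # printed proportions sum to 0.999; renormalized
      prop = c(0.221, 0.137, 0.182, 0.197, 0.117, 0.145) /
        sum(c(0.221, 0.137, 0.182, 0.197, 0.117, 0.145))
    ),
    gender = list(
      type = "categorical",
      levels = c("Male", "Female"),
      prop = c(0.441, 0.559)
    ),
    house = list(
      type = "categorical",
      levels = c("Owned", "Rent", "Other"),
      prop = c(0.762, 0.225, 0.013)
    ),
    srh = list(
      type = "categorical",
      levels = c("Excellent", "Very good", "Good", "Fair", "Poor"),
      prop = c(0.154, 0.355, 0.287, 0.154, 0.050)
    ),
    smoking = list(
      type = "categorical",
      levels = c("Smoker", "Ex smoker", "Non smoker"),
      prop = c(0.197, 0.403, 0.400)
    )
  )
}

# Order in which the latent correlation matrix is indexed (CRP row of the
# published matrix is dropped: CRP is generated through the model, not the
# copula).
copula_variables <- function() {
  c("occupation", "education", "gender", "house", "srh", "smoking",
    "sport", "age", "income", "bmi")
}

# Published pairwise correlations, read as latent-normal (copula)
# correlations between the covariates.
default_latent_correlation <- function() {
  v <- copula_variables()
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  set2 <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set2("education", "occupation", 0.44)
  set2("gender", "occupation", 0.05); set2("gender", "education", 0.05)
  set2("house", "occupation", 0.14); set2("house", "education", 0.16)
  set2("house", "gender", 0.04)
  set2("srh", "occupation", 0.27); set2("srh", "education", 0.26)
  set2("srh", "gender", 0.00); set2("srh", "house", 0.15)
  set2("smoking", "occupation", -0.09); set2("smoking", "education", -0.15)
  set2("smoking", "gender", 0.07); set2("smoking", "house", -0.21)
  set2("smoking", "srh", -0.17)
  set2("sport", "occupation", -0.22); set2("sport", "education", -0.25)
  set2("sport", "gender", -0.11); set2("sport", "house", -0.09)
  set2("sport", "srh", -0.37); set2("sport", "smoking", 0.10)
  set2("age", "occupation", 0.39); set2("age", "education", 0.28)
  set2("age", "gender", -0.04); set2("age", "house", -0.17)
  set2("age", "srh", 0.21); set2("age", "smoking", 0.04)
  set2("age", "sport", -0.30)
  set2("income", "occupation", -0.41); set2("income", "education", -0.33)
  set2("income", "gender", -0.05); set2("income", "house", -0.18)
  set2("income", "srh", -0.20); set2("income", "smoking", 0.11)
  set2("income", "sport", 0.17); set2("income", "age", -0.11)
  set2("bmi", "occupation", 0.06); set2("bmi", "education", 0.12)
  set2("bmi", "gender", 0.00); set2("bmi", "house", 0.06)
  set2("bmi", "srh", 0.23); set2("bmi", "smoking", 0.02)
  set2("bmi", "sport", -0.19); set2("bmi", "age", 0.12)
  set2("bmi", "income", -0.08)
  R
}

#' Nearest positive-definite repair of a correlation matrix
#'
#' Printed, rounded correlation matrices are often slightly non-positive
#' definite. Eigenvalues below a floor are clipped and the matrix is rescaled
#' back to unit diagonal.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param eigen_floor smallest admissible eigenvalue.
#' @return a positive-definite correlation matrix.
#' @keywords internal
nearest_pd_correlation <- function(R, eigen_floor = 1e-8) {
  if (!isSymmetric(unname(R), tol = 1e-12)) {
    stop("correlation matrix must be symmetric")
  }
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eigen_floor) {
    return(R)
  }
  vals <- pmax(e$values, eigen_floor)
  M <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  dimnames(M) <- dimnames(R)
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("correlation matrix not positive definite after repair")
  }
  M
}

# Solve for parent-normal (mu0, sigma0) such that the [lower, upper]-truncated
# normal has the target mean and SD. Needed because truncation at ~2 SD
# shrinks moments materially (e.g. the age margin).
truncnorm_parent <- function(mean, sd, lower, upper) {
  if (!is.finite(lower) && !is.finite(upper)) {
    return(c(mu = mean, sigma = sd))
  }
  moments <- function(mu, sigma) {
    a <- (lower - mu) / sigma
    b <- (upper - mu) / sigma
    pa <- stats::pnorm(a); pb <- stats::pnorm(b)
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    Z <- pb - pa
    m1 <- mu + sigma * (da - db) / Z
    term_a <- if (is.finite(a)) a * da else 0
    term_b <- if (is.finite(b)) b * db else 0
    v <- sigma^2 * (1 + (term_a - term_b) / Z - ((da - db) / Z)^2)
    c(m1, sqrt(v))
  }
  obj <- function(par) {
    m <- moments(par[1], exp(par[2]))
    sum((m - c(mean, sd))^2)
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF map from a uniform to one margin.
margin_quantile <- function(u, spec) {
  switch(spec$type,
    truncnorm = {
      p <- truncnorm_parent(spec$mean, spec$sd, spec$lower, spec$upper)
      pa <- stats::pnorm(spec$lower, p["mu"], p["sigma"])
      pb <- stats::pnorm(spec$upper, p["mu"], p["sigma"])
      stats::qnorm(pa + u * (pb - pa), p["mu"], p["sigma"])
    },
    count = {
      # continuous truncated normal on [lower-0.5, upper+0.5], rounded
      p <- truncnorm_parent(spec$mean, spec$sd, spec$lower - 0.5, spec$upper + 0.5)
      pa <- stats::pnorm(spec$lower - 0.5, p["mu"], p["sigma"])
      pb <- stats::pnorm(spec$upper + 0.5, p["mu"], p["sigma"])
      x <- stats::qnorm(pa + u * (pb - pa), p["mu"], p["sigma"])
      pmin(pmax(round(x), spec$lower), spec$upper)
    },
    lognormal = {
      s2 <- log(1 + (spec$sd / spec$mean)^2)
      mu <- log(spec$mean) - s2 / 2
      stats::qlnorm(u, meanlog = mu, sdlog = sqrt(s2))
    },
    categorical = {
      if (abs(sum(spec$prop) - 1) > 1e-8) stop("category proportions must sum to 1")
      idx <- findInterval(u, cumsum(spec$prop), left.open = TRUE) + 1L
      factor(spec$levels[idx], levels = spec$levels)
    },
    stop("unknown margin type: ", spec$type)
  )
}
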