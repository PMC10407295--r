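# Likelihood, priors, posterior and the unconstrained sampling target.

#' Location--scale Student-t log density
#'
#' @param x evaluation points.
#' @param location location parameter.
#' @param scale scale parameter (> 0).
#' @param nu degrees of freedom (> 0).
#' @return log density values.
#' @export
student_t_logpdf <- function(x, location = 0, scale = 1, nu = 30) {
  if (any(scale <= 0)) stop("scale must be positive")
  if (any(nu <= 0)) stop("nu must be positive")
  r <- (x - location) / scale
  lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi) - log(scale) -
    (nu + 1) / 2 * log1p(r^2 / nu)
}

#' Prior configuration
#'
#' Data-dependent prior constants: the intercept prior is centred at the
#' sample mean of log-CRP with its sample SD as scale, and the same SD scales
#' the half-Cauchy priors on group-deviation SDs and the half-Normal priors
#' on residual-scale parameters. The degrees-of-freedom prior is an
#' exponential (default rate 1/29, i.e. prior mean 30) shifted to nu > 1.
#'
#' @param y response vector (log-CRP) used for \code{mu_y}/\code{sigma_y};
#'   alternatively supply both directly.
#' @param mu_y,sigma_y prior constants.
#' @param nu_rate rate of the exponential prior on \code{nu - nu_lower}.
#' @param nu_lower lower support bound for nu.
#' @return a \code{prior_config} list.
#' @export
prior_config <- function(y = NULL, mu_y = NULL, sigma_y = NULL,
                         nu_rate = 1 / 29, nu_lower = 1) {
  if (!is.null(y)) {
    mu_y <- mean(y)
    sigma_y <- stats::sd(y)
  }
  if (is.null(mu_y) || is.null(sigma_y)) stop("supply y or both mu_y and sigma_y")
  if (sigma_y <= 0) stop("sigma_y must be positive")
  if (nu_rate <= 0) stop("nu_rate must be positive")
  structure(list(mu_y = mu_y, sigma_y = sigma_y,
                 nu_rate = nu_rate, nu_lower = nu_lower),
            class = "prior_config")
}

#' Linear predictor of a parameter set on a design
#'
#' @param params a \code{crp_params} object.
#' @param design design from [encode_design()].
#' @param side \code{"mu"} for the location predictor; \code{"sigma"} for the
#'   log-scale predictor (Model 2 only).
#' @return per-row linear predictor.
#' @export
linear_predictor <- function(params, design, side = c("mu", "sigma")) {
  side <- match.arg(side)
  if (side == "mu") {
    drop(params$beta0 + design$X %*% params$beta_fixed +
           params$u_edu[design$edu] + params$u_occ[design$occ])
  } else {
    if (attr(params, "model") != 2L) {
      stop("sigma-side predictor requires Model 2 parameters")
    }
    drop(params$gamma0 + design$X %*% params$gamma_fixed +
           params$v_edu[design$edu] + params$v_occ[design$occ])
  }
}

#' Model log likelihood
#'
#' Sum of location--scale Student-t log densities with per-row location from
#' the mu-side predictor and scale \code{sigma} (Model 1) or
#' \code{exp(eta_sigma)} (Model 2).
#'
#' @inheritParams linear_predictor
#' @param y response vector.
#' @param model 1 or 2.
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(params, y, design, model = attr(params, "model")) {
  mu <- linear_predictor(params, design, "mu")
  scale_i <- if (as.integer(model) == 1L) params$sigma
             else exp(linear_predictor(params, design, "sigma"))
  sum(student_t_logpdf(y, mu, scale_i, params$nu))
}

half_cauchy_lpdf <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2 / pi) - log(scale) - log1p((x / scale)^2))
}

half_normal_lpdf <- function(x, scale) {
  ifelse(x <= 0, -Inf,
         0.5 * log(2 / pi) - log(scale) - x^2 / (2 * scale^2))
}

#' Model log prior (constrained scale)
#'
#' Intercept: Normal(\code{mu_y}, \code{sigma_y}); fixed-effect
#' coefficients: standard normal; group deviations: Normal(0, group SD);
#' group-deviation SDs: half-Cauchy(0, \code{sigma_y}); residual scale
#' (Model 1) and scale-side deviation SDs (Model 2): half-Normal(0,
#' \code{sigma_y}); Model 2 log-scale intercept: Normal(0, \code{sigma_y});
#' \code{nu - nu_lower}: Exponential(\code{nu_rate}). Out-of-support
#' parameters return \code{-Inf}.
#'
#' @inheritParams log_likelihood
#' @param prior a [prior_config()].
#' @return scalar log prior density.
#' @export
log_prior <- function(params, prior, model = attr(params, "model")) {
  model <- as.integer(model)
  p <- params
  if (p$sd_edu <= 0 || p$sd_occ <= 0 || p$nu <= prior$nu_lower) return(-Inf)
  if (model == 1L && p$sigma <= 0) return(-Inf)
  if (model == 2L && (p$sd_v_edu <= 0 || p$sd_v_occ <= 0)) return(-Inf)
  lp <- stats::dnorm(p$beta0, prior$mu_y, prior$sigma_y, log = TRUE)
  lp <- lp + sum(stats::dnorm(p$beta_fixed, 0, 1, log = TRUE))
  lp <- lp + sum(stats::dnorm(p$u_edu, 0, p$sd_edu, log = TRUE))
  lp <- lp + sum(stats::dnorm(p$u_occ, 0, p$sd_occ, log = TRUE))
  lp <- lp + half_cauchy_lpdf(p$sd_edu, prior$sigma_y)
  lp <- lp + half_cauchy_lpdf(p$sd_occ, prior$sigma_y)
  if (model == 1L) {
    lp <- lp + half_normal_lpdf(p$sigma, prior$sigma_y)
  } else {
    lp <- lp + stats::dnorm(p$gamma0, 0, prior$sigma_y, log = TRUE)
    lp <- lp + sum(stats::dnorm(p$gamma_fixed, 0, 1, log = TRUE))
    lp <- lp + sum(stats::dnorm(p$v_edu, 0, p$sd_v_edu, log = TRUE))
    lp <- lp + sum(stats::dnorm(p$v_occ, 0, p$sd_v_occ, log = TRUE))
    lp <- lp + half_normal_lpdf(p$sd_v_edu, prior$sigma_y)
    lp <- lp + half_normal_lpdf(p$sd_v_occ, prior$sigma_y)
  }
  lp + stats::dexp(p$nu - prior$nu_lower, rate = prior$nu_rate, log = TRUE)
}

#' Unnormalized model log posterior
#'
#' @inheritParams log_prior
#' @param y response vector.
#' @param design design from [encode_design()].
#' @return \code{log_likelihood + log_prior}.
#' @export
log_posterior <- function(params, y, design, prior,
                          model = attr(params, "model")) {
  lp <- log_prior(params, prior, model)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(params, y, design, model)
}

# ---- unconstrained parameterization -----------------------------------------

n_unconstrained <- function(model) if (as.integer(model) == 1L) 33L else 63L

unconstrained_names <- function(model) {
  fe <- fixed_effect_names()
  base <- c("b0", paste0("b.", fe),
            paste0("z_edu.", education_levels()),
            paste0("z_occ.", occupation_levels()),
            "log_sd_edu", "log_sd_occ")
  if (as.integer(model) == 1L) {
    c(base, "log_sigma", "log_nu_m1")
  } else {
    c(base, "g0", paste0("g.", fe),
      paste0("zv_edu.", education_levels()),
      paste0("zv_occ.", occupation_levels()),
      "log_sd_v_edu", "log_sd_v_occ", "log_nu_m1")
  }
}

# reporting-scale parameter names, ordered like the published tables
constrained_names <- function(model) {
  fe <- fixed_effect_names()
  edu <- paste0("Education: ", education_levels())
  occ <- paste0("Occupation: ", occupation_levels())
  if (as.integer(model) == 1L) {
    c("Intercept", fe, "Std Education (Intercept)",
      "Std Occupation (Intercept)", "sigma", "nu", edu, occ)
  } else {
    c("Intercept", "sigma_Intercept", fe, paste0("sigma_", fe),
      "Std Education (Intercept)", "Std Occupation (Intercept)",
      "sigma_Std Education (Intercept)", "sigma_Std Occupation (Intercept)",
      "nu", edu, occ, paste0("sigma_", edu), paste0("sigma_", occ))
  }
}

# params object -> unconstrained vector
pack_params <- function(params, prior, model = attr(params, "model")) {
  model <- as.integer(model)
  th <- c(params$beta0, params$beta_fixed,
          params$u_edu / params$sd_edu, params$u_occ / params$sd_occ,
          log(params$sd_edu), log(params$sd_occ))
  if (model == 1L) {
    th <- c(th, log(params$sigma), log(params$nu - prior$nu_lower))
  } else {
    th <- c(th, params$gamma0, params$gamma_fixed,
            params$v_edu / params$sd_v_edu, params$v_occ / params$sd_v_occ,
            log(params$sd_v_edu), log(params$sd_v_occ),
            log(params$nu - prior$nu_lower))
  }
  stats::setNames(as.numeric(th), unconstrained_names(model))
}

# unconstrained vector -> params object
unpack_params <- function(theta, prior, model) {
  model <- as.integer(model)
  theta <- unname(theta)
  b0 <- theta[1]
  b <- theta[2:14]
  ze <- theta[15:20]
  zo <- theta[21:29]
  se <- exp(theta[30]); so <- exp(theta[31])
  if (model == 1L) {
    model1_params(b0, b, se * ze, so * zo, se, so,
                  sigma = exp(theta[32]),
                  nu = prior$nu_lower + exp(theta[33]))
  } else {
    g0 <- theta[32]
    g <- theta[33:45]
    zve <- theta[46:51]
    zvo <- theta[52:60]
    sve <- exp(theta[61]); svo <- exp(theta[62])
    model2_params(b0, b, se * ze, so * zo, se, so,
                  g0, g, sve * zve, svo * zvo, sve, svo,
                  nu = prior$nu_lower + exp(theta[63]))
  }
}

# unconstrained vector -> named reporting-scale vector
constrain_theta <- function(theta, prior, model) {
  p <- unpack_params(theta, prior, model)
  v <- if (as.integer(model) == 1L) {
    c(p$beta0, p$beta_fixed, p$sd_edu, p$sd_occ, p$sigma, p$nu,
      p$u_edu, p$u_occ)
  } else {
    c(p$beta0, p$gamma0, p$beta_fixed, p$gamma_fixed,
      p$sd_edu, p$sd_occ, p$sd_v_edu, p$sd_v_occ, p$nu,
      p$u_edu, p$u_occ, p$v_edu, p$v_occ)
  }
  stats::setNames(as.numeric(v), constrained_names(model))
}

#' Build the unconstrained sampling target
#'
#' Returns the log posterior and its analytic gradient as functions of the
#' unconstrained parameter vector (log-transformed positive parameters with
#' Jacobians; non-centered group deviations). Coordinates listed in
#' \code{fixed} are pinned at the supplied values and dropped from the free
#' vector, which gives low-dimensional targets for exact cross-checks.
#'
#' @param y response vector.
#' @param design design from [encode_design()].
#' @param prior a [prior_config()].
#' @param model 1 or 2.
#' @param fixed optional named numeric vector of unconstrained coordinates to
#'   pin (names from the internal layout, e.g. \code{"log_sigma"}).
#' @return list with \code{lp}, \code{grad}, \code{n_par}, \code{names},
#'   \code{constrain} and \code{assemble}.
#' @export
make_target <- function(y, design, prior, model = 1, fixed = NULL) {
  model <- as.integer(model)
  nm <- unconstrained_names(model)
  full <- stats::setNames(numeric(length(nm)), nm)
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% nm)) {
      stop("unknown fixed coordinates: ",
           paste(setdiff(names(fixed), nm), collapse = ", "))
    }
    full[names(fixed)] <- fixed
  }
  free <- which(!(nm %in% names(fixed)))
  Xm <- design$X
  edu0 <- design$edu - 1L
  occ0 <- design$occ - 1L
  assemble <- function(th_free) {
    full[free] <- th_free
    full
  }
  list(
    lp = function(th_free) {
      th <- assemble(th_free)
      crp_lp_grad_cpp(th, y, Xm, edu0, occ0, model,
                      prior$mu_y, prior$sigma_y, prior$nu_rate,
                      prior$nu_lower, FALSE)$lp
    },
    grad = function(th_free) {
      th <- assemble(th_free)
      out <- crp_lp_grad_cpp(th, y, Xm, edu0, occ0, model,
                             prior$mu_y, prior$sigma_y, prior$nu_rate,
                             prior$nu_lower, TRUE)
      list(lp = out$lp, grad = as.numeric(out$grad)[free])
    },
    n_par = length(free),
    names = nm[free],
    constrain = function(th_free) {
      constrain_theta(assemble(th_free), prior, model)
    },
    assemble = assemble,
    model = model,
    prior = prior
  )
}

#' Gradient of the unconstrained log posterior
#'
#' Analytic gradient in the unconstrained parameterization; the reference
#' check against central finite differences lives in the test suite.
#'
#' @param theta unconstrained parameter vector (full layout).
#' @inheritParams make_target
#' @return list with \code{lp} and \code{grad}.
#' @export
gradient <- function(theta, y, design, prior, model = 1) {
  out <- crp_lp_grad_cpp(theta, y, design$X, design$edu - 1L,
                         design$occ - 1L, as.integer(model),
                         prior$mu_y, prior$sigma_y, prior$nu_rate,
                         prior$nu_lower, TRUE)
  list(lp = out$lp, grad = as.numeric(out$grad))
}

# pure-R unconstrained log posterior: the likelihood/prior composed with the
# transform, used to validate the compiled path
log_posterior_unconstrained <- function(theta, y, design, prior, model) {
  model <- as.integer(model)
  p <- unpack_params(theta, prior, model)
  lp <- log_likelihood(p, y, design, model) +
    stats::dnorm(p$beta0, prior$mu_y, prior$sigma_y, log = TRUE) +
    sum(stats::dnorm(p$beta_fixed, 0, 1, log = TRUE)) +
    sum(stats::dnorm(p$u_edu / p$sd_edu, log = TRUE)) +
    sum(stats::dnorm(p$u_occ / p$sd_occ, log = TRUE)) +
    half_cauchy_lpdf(p$sd_edu, prior$sigma_y) + log(p$sd_edu) +
    half_cauchy_lpdf(p$sd_occ, prior$sigma_y) + log(p$sd_occ) +
    stats::dexp(p$nu - prior$nu_lower, prior$nu_rate, log = TRUE) +
    log(p$nu - prior$nu_lower)
  if (model == 1L) {
    lp + half_normal_lpdf(p$sigma, prior$sigma_y) + log(p$sigma)
  } else {
    lp + stats::dnorm(p$gamma0, 0, prior$sigma_y, log = TRUE) +
      sum(stats::dnorm(p$gamma_fixed, 0, 1, log = TRUE)) +
      sum(stats::dnorm(p$v_edu / p$sd_v_edu, log = TRUE)) +
      sum(stats::dnorm(p$v_occ / p$sd_v_occ, log = TRUE)) +
      half_normal_lpdf(p$sd_v_edu, prior$sigma_y) + log(p$sd_v_edu) +
      half_normal_lpdf(p$sd_v_occ, prior$sigma_y) + log(p$sd_v_occ)
  }
}
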