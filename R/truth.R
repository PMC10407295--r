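# Parameter containers for the two models, plus the published posterior means
# used as generating truth in recovery simulations.

fixed_effect_names <- function() {
  c("Gender (Female)", "Rent", "Other",
    "Very good", "Good", "Fair", "Poor",
    "Ex smoker", "Non smoker",
    "Sport Activity", "Age", "Income", "BMI")
}

education_levels <- function() default_marginals()$education$levels
occupation_levels <- function() default_marginals()$occupation$levels

#' Construct a Model 1 parameter set
#'
#' Model 1 is a hierarchical Student-t regression: the location of log-CRP is
#' a linear function of fixed effects plus education and occupation group
#' deviations; the residual scale \code{sigma} is constant.
#'
#' @param beta0 intercept.
#' @param beta_fixed numeric vector of 13 fixed-effect coefficients, ordered
#'   as gender, house ownership, self-rated health and smoking dummies
#'   followed by the z-scored sport, age, income and BMI slopes.
#' @param u_edu,u_occ group deviations for the 6 education and 9 occupation
#'   categories.
#' @param sd_edu,sd_occ standard deviations of the group deviations.
#' @param sigma residual scale of the Student-t likelihood.
#' @param nu Student-t degrees of freedom (> 1).
#' @return an object of class \code{crp_params}.
#' @export
model1_params <- function(beta0, beta_fixed, u_edu, u_occ,
                          sd_edu, sd_occ, sigma, nu) {
  stopifnot(length(beta_fixed) == 13, length(u_edu) == 6, length(u_occ) == 9,
            sd_edu > 0, sd_occ > 0, sigma > 0, nu > 0)
  structure(
    list(beta0 = beta0,
         beta_fixed = stats::setNames(beta_fixed, fixed_effect_names()),
         u_edu = stats::setNames(u_edu, education_levels()),
         u_occ = stats::setNames(u_occ, occupation_levels()),
         sd_edu = sd_edu, sd_occ = sd_occ, sigma = sigma, nu = nu),
    class = "crp_params", model = 1L)
}

#' Construct a Model 2 parameter set
#'
#' Model 2 replaces the constant residual scale with a log-linear model:
#' \code{ln sigma_i} has its own intercept \code{gamma0}, fixed-effect
#' coefficients and education/occupation deviations.
#'
#' @inheritParams model1_params
#' @param gamma0 intercept of the log-scale predictor.
#' @param gamma_fixed 13 scale-side fixed-effect coefficients (same order as
#'   \code{beta_fixed}).
#' @param v_edu,v_occ scale-side group deviations.
#' @param sd_v_edu,sd_v_occ standard deviations of the scale-side deviations.
#' @return an object of class \code{crp_params}.
#' @export
model2_params <- function(beta0, beta_fixed, u_edu, u_occ, sd_edu, sd_occ,
                          gamma0, gamma_fixed, v_edu, v_occ,
                          sd_v_edu, sd_v_occ, nu) {
  stopifnot(length(beta_fixed) == 13, length(u_edu) == 6, length(u_occ) == 9,
            length(gamma_fixed) == 13, length(v_edu) == 6, length(v_occ) == 9,
            sd_edu > 0, sd_occ > 0, sd_v_edu > 0, sd_v_occ > 0, nu > 0)
  structure(
    list(beta0 = beta0,
         beta_fixed = stats::setNames(beta_fixed, fixed_effect_names()),
         u_edu = stats::setNames(u_edu, education_levels()),
         u_occ = stats::setNames(u_occ, occupation_levels()),
         sd_edu = sd_edu, sd_occ = sd_occ,
         gamma0 = gamma0,
         gamma_fixed = stats::setNames(gamma_fixed, fixed_effect_names()),
         v_edu = stats::setNames(v_edu, education_levels()),
         v_occ = stats::setNames(v_occ, occupation_levels()),
         sd_v_edu = sd_v_edu, sd_v_occ = sd_v_occ, nu = nu),
    class = "crp_params", model = 2L)
}

#' Published posterior means as generating truth
#'
#' Returns the published posterior-mean estimates for the homoscedastic
#' (Model 1) or distributional (Model 2) fit of the UKHLS analysis, packaged
#' as a parameter set. These values are the standard generating truth for
#' parameter-recovery simulations against the original analysis.
#'
#' @param model 1 or 2.
#' @return a \code{crp_params} object.
#' @export
published_truth <- function(model = 1) {
  model <- as.integer(model)
  if (model == 1L) {
    model1_params(
      beta0 = 0.379,
      beta_fixed = c(0.150, 0.062, 0.063, 0.079, 0.084, 0.198, 0.333,
                     -0.221, -0.257, -0.075, 0.085, -0.015, 0.386),
      u_edu = c(-0.057, -0.038, 0.003, -0.034, 0.038, 0.086),
      u_occ = c(-0.043, 0.006, 0.0001, -0.023, -0.052, 0.007, 0.030,
                0.026, 0.052),
      sd_edu = 0.087, sd_occ = 0.055, sigma = 0.876, nu = 9.747)
  } else if (model == 2L) {
    model2_params(
      beta0 = 0.370,
      beta_fixed = c(0.159, 0.059, 0.058, 0.083, 0.090, 0.203, 0.338,
                     -0.220, -0.261, -0.058, 0.080, -0.015, 0.386),
      u_edu = c(-0.052, -0.032, 0.006, -0.029, 0.034, 0.080),
      u_occ = c(-0.043, 0.004, -0.0000, -0.024, -0.056, 0.007, 0.029,
                0.027, 0.058),
      sd_edu = 0.079, sd_occ = 0.057,
      gamma0 = -0.155,
      gamma_fixed = c(0.022, 0.012, 0.008, 0.047, 0.056, 0.095, 0.064,
                      -0.058, -0.089, -0.089, -0.027, -0.004, -0.040),
      v_edu = c(-0.006, -0.007, 0.007, -0.015, 0.017, 0.004),
      v_occ = c(-0.020, 0.037, -0.028, -0.007, -0.057, 0.011, 0.016,
                -0.009, 0.057),
      sd_v_edu = 0.024, sd_v_occ = 0.052, nu = 10.357)
  } else {
    stop("model must be 1 or 2")
  }
}
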