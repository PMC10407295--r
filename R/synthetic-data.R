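# Gaussian-copula generator for survey-like synthetic data.

#' Generator configuration
#'
#' Bundles everything the synthetic-data generator needs: sample size,
#' marginal calibration targets (means/SDs for continuous variables, category
#' proportions for categorical ones), the latent-normal correlation matrix
#' between covariates, the generating parameter set, and a seed.
#'
#' @param n number of records.
#' @param marginals per-variable marginal specifications; defaults to the
#'   published summary statistics of the analysis sample.
#' @param latent_correlation symmetric unit-diagonal matrix over the 10
#'   covariates; defaults to the published correlation matrix read on the
#'   latent-normal scale. Repaired to the nearest positive-definite
#'   correlation matrix if needed.
#' @param truth generating parameter set (see [model1_params()],
#'   [published_truth()]).
#' @param seed integer seed; the generator is deterministic given the config.
#' @return a \code{generator_config} list.
#' @export
generator_config <- function(n = 2000,
                             marginals = default_marginals(),
                             latent_correlation = default_latent_correlation(),
                             truth = published_truth(1),
                             seed = 1L) {
  if (n < 1) stop("n must be at least 1")
  vars <- copula_variables()
  if (!all(vars %in% names(marginals))) {
    stop("marginals missing variables: ",
         paste(setdiff(vars, names(marginals)), collapse = ", "))
  }
  if (!identical(dim(latent_correlation), c(length(vars), length(vars)))) {
    stop("latent_correlation must be ", length(vars), "x", length(vars))
  }
  if (any(abs(diag(latent_correlation) - 1) > 1e-12)) {
    stop("latent_correlation must have unit diagonal")
  }
  R <- nearest_pd_correlation(latent_correlation)
  for (v in vars) {
    sp <- marginals[[v]]
    if (sp$type == "categorical" && abs(sum(sp$prop) - 1) > 1e-8) {
      stop("category proportions for ", v, " must sum to 1")
    }
  }
  structure(list(n = as.integer(n), marginals = marginals,
                 latent_correlation = R, truth = truth,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate covariates by a Gaussian copula
#'
#' Draws a latent multivariate normal with the configured correlation matrix
#' and maps each margin through its inverse CDF: truncated normals matched to
#' the target mean/SD (parent moments solved numerically), a lognormal income
#' margin, sport activity rounded to the 0--10 scale, and categorical margins
#' thresholded at the cumulative target proportions. Household composition
#' and body size (height/weight consistent with the BMI margin) are appended
#' to complete the raw-table schema. Deterministic given the config seed.
#'
#' @param config a [generator_config()].
#' @return a data.frame with one row per person and the raw-table columns
#'   (\code{crp} initialized to \code{NA}).
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  vars <- copula_variables()
  n <- config$n
  set.seed(config$seed)
  L <- chol(config$latent_correlation)
  Z <- matrix(stats::rnorm(n * length(vars)), nrow = n) %*% L
  colnames(Z) <- vars
  U <- stats::pnorm(Z)
  out <- list()
  for (v in vars) out[[v]] <- margin_quantile(U[, v], config$marginals[[v]])
  df <- data.frame(crp = rep(NA_real_, n))
  df$occupation <- out$occupation
  df$education <- out$education
  df$gender <- out$gender
  df$house <- out$house
  df$srh <- out$srh
  df$smoking <- out$smoking
  df$sport <- out$sport
  df$age <- out$age
  df$income <- out$income
  # household composition: only needed to exercise income equivalization
  df$n_adults <- sample(c(1L, 2L, 3L), n, replace = TRUE,
                        prob = c(0.30, 0.55, 0.15))
  df$n_children <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                          prob = c(0.60, 0.25, 0.15))
  # height by gender; weight back-solved so that weight/(height/100)^2
  # reproduces the copula BMI margin
  mu_h <- ifelse(df$gender == "Male", 175.3, 161.9)
  df$height_cm <- stats::rnorm(n, mu_h, 7.2)
  df$weight_kg <- out$bmi * (df$height_cm / 100)^2
  attr(df, "latent") <- Z
  df
}

#' Generate log-CRP responses under the model
#'
#' Draws each response from a location--scale Student-t: the location is the
#' model's linear predictor built from the (z-standardized) covariates, the
#' scale is constant (\code{sigma}, Model 1) or \code{exp} of the scale-side
#' linear predictor (Model 2), and the degrees of freedom are \code{nu}.
#'
#' @param covariates a complete raw table (no missing values).
#' @param truth generating \code{crp_params}.
#' @param model 1 or 2; must match \code{truth}.
#' @param seed integer seed.
#' @param oecd_scale equivalence scale passed to the design encoding.
#' @return numeric vector of log-CRP values (natural log of mg/L).
#' @export
generate_response <- function(covariates, truth, model = attr(truth, "model"),
                              seed = 1L, oecd_scale = "modified") {
  model <- as.integer(model)
  if (!identical(model, attr(truth, "model"))) {
    stop("truth parameter set is for model ", attr(truth, "model"))
  }
  if (truth$nu <= 0) stop("nu must be positive")
  analytic <- prepare_analytic(covariates, oecd_scale = oecd_scale,
                               require_crp = FALSE)
  design <- encode_design(analytic)
  mu <- linear_predictor(truth, design, side = "mu")
  scale_i <- if (model == 1L) {
    if (truth$sigma < 0) stop("sigma must be non-negative")
    rep(truth$sigma, nrow(design$X))
  } else {
    exp(linear_predictor(truth, design, side = "sigma"))
  }
  set.seed(as.integer(seed))
  mu + scale_i * stats::rt(nrow(design$X), df = truth$nu)
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: covariates by [generate_covariates()], responses by
#' [generate_response()] under the configured truth, CRP set to \code{exp(y)}.
#'
#' @param config a [generator_config()].
#' @return raw-table data.frame with the \code{crp} column filled.
#' @export
generate_dataset <- function(config) {
  df <- generate_covariates(config)
  y <- generate_response(df, config$truth, seed = config$seed + 1L)
  df$crp <- exp(y)
  attr(df, "latent") <- NULL
  df
}

#' Generate the raw fixture with the study's missingness pattern
#'
#' Emits a raw table shaped like the pre-exclusion study sample: 9896
#' records, of which exactly 521 are missing CRP, a disjoint 283 have
#' inapplicable height/weight (so BMI cannot be computed), a further disjoint
#' 132 are missing one other covariate, and the remaining 8960 are complete.
#'
#' @param seed integer seed.
#' @param truth generating parameter set for the CRP responses.
#' @return raw-table data.frame with 9896 rows.
#' @export
generate_raw_fixture <- function(seed = 1L, truth = published_truth(1)) {
  n_total <- 9896L
  n_crp_na <- 521L
  n_bmi_na <- 283L
  n_cov_na <- 132L
  cfg <- generator_config(n = n_total, truth = truth, seed = as.integer(seed))
  df <- generate_dataset(cfg)
  set.seed(as.integer(seed) + 2L)
  idx <- sample.int(n_total, n_crp_na + n_bmi_na + n_cov_na)
  i_crp <- idx[seq_len(n_crp_na)]
  i_bmi <- idx[n_crp_na + seq_len(n_bmi_na)]
  i_cov <- idx[n_crp_na + n_bmi_na + seq_len(n_cov_na)]
  df$crp[i_crp] <- NA_real_
  df$height_cm[i_bmi] <- NA_real_
  df$weight_kg[i_bmi] <- NA_real_
  # spread residual missingness over three covariates
  which_col <- rep_len(c("income", "smoking", "sport"), n_cov_na)
  df$income[i_cov[which_col == "income"]] <- NA_real_
  df$smoking[i_cov[which_col == "smoking"]] <- NA
  df$sport[i_cov[which_col == "sport"]] <- NA_real_
  df
}

#' Write a raw table to CSV with a sidecar JSON manifest
#'
#' Missing cells are encoded as empty fields. The sidecar records the
#' generator seed and sample size so every file is traceable.
#'
#' @param raw raw-table data.frame.
#' @param path output CSV path.
#' @param config optional [generator_config()] recorded in the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_raw_table <- function(raw, path, config = NULL) {
  utils::write.csv(raw, path, row.names = FALSE, na = "")
  meta <- list(n = nrow(raw), columns = names(raw))
  if (!is.null(config)) {
    meta$seed <- config$seed
    meta$generator_n <- config$n
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a raw table written by [write_raw_table()]
#'
#' @param path CSV path.
#' @return raw-table data.frame with categorical columns re-levelled.
#' @export
read_raw_table <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  m <- default_marginals()
  for (v in c("occupation", "education", "gender", "house", "srh", "smoking")) {
    df[[v]] <- factor(df[[v]], levels = m[[v]]$levels)
  }
  df
}
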