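# Shared fixtures, built in code. Small fits are cached so several test
# files can reuse them without refitting.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small complete synthetic analytic table
small_analytic <- function(n = 400, model = 1, seed = 99) {
  cached(paste("analytic", n, model, seed, sep = "_"), {
    cfg <- generator_config(n = n, truth = published_truth(model), seed = seed)
    raw <- generate_dataset(cfg)
    prepare_analytic(apply_exclusions(raw)$data)
  })
}

# small fitted model, enough draws for structural checks
small_fit <- function(model = 1) {
  cached(paste0("fit_model", model), {
    an <- small_analytic(400, model)
    fit_crp(an, model = model,
            control = sampler_control(n_chains = 2, n_iterations = 500,
                                      n_warmup = 250),
            seed = 123)
  })
}

# a three-row design with all-zero fixed-effect columns, for toy posteriors
toy_design <- function(y = c(0.2, 1.1, -0.7)) {
  X <- matrix(0, length(y), 13)
  colnames(X) <- crpdist:::fixed_effect_names()
  list(X = X, edu = rep_len(1:6, length(y)), occ = rep_len(1:9, length(y)),
       y = y, n = length(y))
}

# random parameter sets strictly inside the support
random_params <- function(model = 1, seed = 1) {
  set.seed(seed)
  if (model == 1) {
    model1_params(rnorm(1), rnorm(13, 0, 0.3), rnorm(6, 0, 0.1),
                  rnorm(9, 0, 0.1), sd_edu = runif(1, 0.05, 0.3),
                  sd_occ = runif(1, 0.05, 0.3), sigma = runif(1, 0.5, 1.5),
                  nu = runif(1, 3, 40))
  } else {
    model2_params(rnorm(1), rnorm(13, 0, 0.3), rnorm(6, 0, 0.1),
                  rnorm(9, 0, 0.1), sd_edu = runif(1, 0.05, 0.3),
                  sd_occ = runif(1, 0.05, 0.3), gamma0 = rnorm(1, -0.2, 0.2),
                  gamma_fixed = rnorm(13, 0, 0.1), v_edu = rnorm(6, 0, 0.05),
                  v_occ = rnorm(9, 0, 0.05), sd_v_edu = runif(1, 0.02, 0.2),
                  sd_v_occ = runif(1, 0.02, 0.2), nu = runif(1, 3, 40))
  }
}

# standard-normal HMC target in d dimensions
normal_target <- function(d = 1, mean = 0, sd = 1) {
  list(
    lp = function(th) -0.5 * sum((th - mean)^2) / sd^2,
    grad = function(th) list(lp = -0.5 * sum((th - mean)^2) / sd^2,
                             grad = -(th - mean) / sd^2),
    n_par = d
  )
}
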