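# Gaussian-copula generator: calibration, determinism, fixture shape.

test_that("generator is deterministic given config and seed", {
  cfg <- generator_config(n = 500, seed = 17)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_dataset(generator_config(n = 500, seed = 18))))
})

test_that("categorical margins hit their target proportions", {
  cfg <- generator_config(n = 10000, seed = 5)
  cov <- generate_covariates(cfg)
  expect_lt(abs(mean(cov$gender == "Female") - 0.559), 0.02)
  m <- default_marginals()
  for (v in c("occupation", "education", "house", "srh", "smoking")) {
    p_hat <- as.numeric(prop.table(table(cov[[v]])))
    expect_lt(max(abs(p_hat - m[[v]]$prop)), 0.01)
  }
})

test_that("latent correlation between education and occupation is preserved", {
  cfg <- generator_config(n = 10000, seed = 5)
  cov <- generate_covariates(cfg)
  Z <- attr(cov, "latent")
  expect_lt(abs(cor(Z[, "education"], Z[, "occupation"]) - 0.44), 0.05)
})

test_that("continuous margins match target moments at large n", {
  cfg <- generator_config(n = 1e5, seed = 5)
  cov <- generate_covariates(cfg)
  m <- default_marginals()
  check <- function(x, target_mean, target_sd) {
    expect_lt(abs(mean(x) - target_mean) / target_mean, 0.02)
    expect_lt(abs(sd(x) - target_sd) / target_sd, 0.02)
  }
  check(cov$sport, m$sport$mean, m$sport$sd)
  check(cov$age, m$age$mean, m$age$sd)
  check(cov$income, m$income$mean, m$income$sd)
  check(compute_bmi(cov$weight_kg, cov$height_cm), m$bmi$mean, m$bmi$sd)
  expect_true(all(cov$sport %in% 0:10))
  expect_true(all(cov$age >= 16 & cov$age <= 98))
  expect_true(all(cov$income > 0))
})

test_that("non-positive-definite printed correlations are repaired", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9   # not PD
  Rp <- nearest_pd_correlation(R)
  ev <- eigen(Rp, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(diag(Rp), rep(1, 3))
  expect_error(nearest_pd_correlation(matrix(c(1, 0.2, 0.3, 1), 2, 2)),
               "symmetric")
})

test_that("responses follow the generating Student-t location-scale law", {
  cfg <- generator_config(n = 1e5, truth = published_truth(1), seed = 21)
  cov <- generate_covariates(cfg)
  truth <- published_truth(1)
  y <- generate_response(cov, truth, seed = 22)
  an <- prepare_analytic(cov, require_crp = FALSE)
  de <- encode_design(an)
  mu <- linear_predictor(truth, de, "mu")
  # Student-t variance: sd = sigma * sqrt(nu / (nu - 2))
  expect_lt(abs(sd(y - mu) - 0.876 * sqrt(9.747 / 7.747)), 0.03)
})

test_that("degenerate scale collapses responses onto the linear predictor", {
  cov <- generate_covariates(generator_config(n = 50, seed = 3))
  tz <- model1_params(2.5, rep(0, 13), rep(0, 6), rep(0, 9),
                      1e-6, 1e-6, sigma = 1e-12, nu = 30)
  y <- generate_response(cov, tz, seed = 4)
  expect_lt(max(abs(y - 2.5)), 1e-8)
})

test_that("a scale model with zero coefficients reduces to the constant-scale model", {
  cfg <- generator_config(n = 1e5, seed = 21)
  cov <- generate_covariates(cfg)
  t1 <- published_truth(1)
  t2 <- model2_params(t1$beta0, t1$beta_fixed, t1$u_edu, t1$u_occ,
                      t1$sd_edu, t1$sd_occ, gamma0 = log(t1$sigma),
                      gamma_fixed = rep(0, 13), v_edu = rep(0, 6),
                      v_occ = rep(0, 9), sd_v_edu = 0.01, sd_v_occ = 0.01,
                      nu = t1$nu)
  y1 <- generate_response(cov, t1, seed = 31)
  y2 <- generate_response(cov, t2, seed = 32)
  expect_lt(abs(mean(y1) - mean(y2)), 0.02)
  expect_lt(abs(sd(y1) / sd(y2) - 1), 0.02)
})

test_that("response generation rejects invalid scale parameters", {
  cov <- generate_covariates(generator_config(n = 20, seed = 3))
  bad <- published_truth(1)
  bad$nu <- -1
  expect_error(generate_response(cov, bad, seed = 1), "nu")
  expect_error(model1_params(0, rep(0, 13), rep(0, 6), rep(0, 9),
                             0.1, 0.1, sigma = -1, nu = 10))
})

test_that("raw fixture reproduces the study's missingness pattern", {
  fx <- generate_raw_fixture(seed = 7)
  expect_equal(nrow(fx), 9896)
  crp_na <- is.na(fx$crp)
  bmi_na <- is.na(fx$height_cm) | is.na(fx$weight_kg)
  cov_na <- is.na(fx$income) | is.na(fx$smoking) | is.na(fx$sport)
  expect_equal(sum(crp_na), 521)
  expect_equal(sum(!crp_na & bmi_na), 283)
  expect_equal(sum(!crp_na & !bmi_na & cov_na), 132)
  # pairwise disjoint missingness sets
  expect_equal(sum(crp_na | bmi_na | cov_na), 521 + 283 + 132)
  complete <- !(crp_na | bmi_na | cov_na)
  expect_false(anyNA(fx[complete, ]))
  expect_true(all(fx$crp[!crp_na] > 0))
})

test_that("raw tables round-trip through CSV with empty-field missing cells", {
  fx <- generate_raw_fixture(seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_table(fx, path, generator_config(n = 9896, seed = 7))
  back <- read_raw_table(path)
  expect_equal(nrow(back), nrow(fx))
  expect_equal(sum(is.na(back$crp)), 521)
  expect_equal(levels(back$occupation), levels(fx$occupation))
  expect_equal(back$crp, fx$crp, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("fitting recovers generating fixed effects across replicates", {
  # scaled-down generative-consistency check: 90% central intervals should
  # cover the generating fixed coefficients at roughly the nominal rate
  truth <- published_truth(1)
  covered <- 0L
  total <- 0L
  for (rep in 1:5) {
    cfg <- generator_config(n = 1200, truth = truth, seed = 300 + rep)
    an <- prepare_analytic(apply_exclusions(generate_dataset(cfg))$data)
    fit <- fit_crp(an, model = 1,
                   control = sampler_control(n_chains = 2, n_iterations = 600,
                                             n_warmup = 300),
                   seed = 400 + rep)
    draws <- crpdist:::pooled_draws(fit)
    for (p in crpdist:::fixed_effect_names()) {
      ci <- quantile(draws[, p], c(0.05, 0.95), type = 8)
      covered <- covered + (truth$beta_fixed[[p]] >= ci[1] &&
                              truth$beta_fixed[[p]] <= ci[2])
      total <- total + 1L
    }
  }
  expect_gte(covered / total, 0.8)
})
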