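# Likelihood, priors, posterior, gradients.

test_that("Student-t log density matches closed forms and the stats oracle", {
  # Cauchy (nu = 1) peak density is 1/pi
  expect_equal(student_t_logpdf(0, 0, 1, 1), log(1 / pi), tolerance = 1e-12)
  # large-nu limit approaches the normal density
  x <- seq(-3, 3, by = 0.5)
  expect_lt(max(abs(student_t_logpdf(x, 0, 1, 1e6) -
                      dnorm(x, log = TRUE))), 1e-4)
  # cross-check against dt on the standardized scale
  set.seed(2)
  for (i in 1:5) {
    loc <- rnorm(1); sc <- runif(1, 0.2, 3); nu <- runif(1, 1, 50)
    expect_equal(student_t_logpdf(x, loc, sc, nu),
                 dt((x - loc) / sc, nu, log = TRUE) - log(sc),
                 tolerance = 1e-12)
  }
  # location-scale family: depends only on (x - loc)/scale, minus log scale
  expect_equal(student_t_logpdf(5, 3, 2, 7),
               student_t_logpdf(1, 0, 1, 7) - log(2))
  expect_error(student_t_logpdf(0, 0, -1, 5), "scale")
  expect_error(student_t_logpdf(0, 0, 1, 0), "nu")
})

test_that("linear predictor is additive and row-wise", {
  de <- toy_design(y = rnorm(9))
  p0 <- model1_params(2.2, rep(0, 13), rep(0, 6), rep(0, 9), 0.1, 0.1, 1, 10)
  expect_equal(linear_predictor(p0, de, "mu"), rep(2.2, de$n))
  # single dummy plus group deviations add up
  de1 <- toy_design(y = 0)
  de1$X[1, "Rent"] <- 1
  de1$edu <- 2L; de1$occ <- 3L
  p1 <- random_params(1, seed = 4)
  expect_equal(linear_predictor(p1, de1, "mu"),
               p1$beta0 + p1$beta_fixed[["Rent"]] + p1$u_edu[[2]] + p1$u_occ[[3]],
               ignore_attr = TRUE)
  # permuting rows permutes the predictor identically
  an <- small_analytic(400)
  de2 <- encode_design(an)
  perm <- sample(de2$n)
  de2p <- list(X = de2$X[perm, ], edu = de2$edu[perm], occ = de2$occ[perm],
               y = de2$y[perm], n = de2$n)
  expect_equal(linear_predictor(p1, de2, "mu")[perm],
               linear_predictor(p1, de2p, "mu"))
  expect_error(linear_predictor(p1, de2, "sigma"), "Model 2")
})

test_that("log likelihood sums per-row Student-t terms", {
  de1 <- toy_design(y = 0.7)
  p <- random_params(1, seed = 5)
  mu <- linear_predictor(p, de1, "mu")
  expect_equal(log_likelihood(p, 0.7, de1),
               student_t_logpdf(0.7, mu, p$sigma, p$nu))
  # doubling the dataset doubles the value
  an <- small_analytic(400)
  de <- encode_design(an)
  de2 <- list(X = rbind(de$X, de$X), edu = c(de$edu, de$edu),
              occ = c(de$occ, de$occ), y = c(de$y, de$y), n = 2L * de$n)
  expect_equal(log_likelihood(p, de2$y, de2), 2 * log_likelihood(p, de$y, de))
})

test_that("scale model nests the constant-scale model at likelihood level", {
  an <- small_analytic(400)
  de <- encode_design(an)
  for (seed in 1:3) {
    p1 <- random_params(1, seed = seed)
    p2 <- model2_params(p1$beta0, p1$beta_fixed, p1$u_edu, p1$u_occ,
                        p1$sd_edu, p1$sd_occ, gamma0 = log(p1$sigma),
                        gamma_fixed = rep(0, 13), v_edu = rep(0, 6),
                        v_occ = rep(0, 9), sd_v_edu = 0.1, sd_v_occ = 0.1,
                        nu = p1$nu)
    expect_equal(log_likelihood(p2, de$y, de), log_likelihood(p1, de$y, de),
                 tolerance = 1e-10)
  }
})

test_that("likelihood approaches the Gaussian limit as nu grows", {
  an <- small_analytic(400)
  de <- encode_design(an)
  p <- published_truth(1)   # residuals on the generating scale
  p$nu <- 1e6
  mu <- linear_predictor(p, de, "mu")
  gauss <- sum(dnorm(de$y, mu, p$sigma, log = TRUE))
  expect_lt(abs(log_likelihood(p, de$y, de) - gauss), 1e-3)
})

test_that("log prior matches its stated components", {
  pr <- prior_config(mu_y = 0.44, sigma_y = 1.09)
  p <- random_params(1, seed = 7)
  # exponential nu prior: shifting nu changes the log prior linearly in rate
  p30 <- p; p30$nu <- 30
  p59 <- p; p59$nu <- 59
  expect_equal(log_prior(p30, pr) - log_prior(p59, pr), (1 / 29) * 29,
               tolerance = 1e-12)
  # at nu = 30 the nu term itself is log(rate) - rate * 29
  expect_equal(dexp(29, 1 / 29, log = TRUE), log(1 / 29) - 1, tolerance = 1e-12)
  # zeroing the fixed effects adds the standard-normal peak for 13 terms
  pz <- p; pz$beta_fixed[] <- 0
  expect_equal(log_prior(pz, pr) - log_prior(p, pr),
               sum(p$beta_fixed^2) / 2, tolerance = 1e-10)
  # out-of-support scale yields -Inf, not an error
  pneg <- p; pneg$sigma <- -1
  expect_identical(log_prior(pneg, pr), -Inf)
  pnu <- p; pnu$nu <- 0.5
  expect_identical(log_prior(pnu, pr), -Inf)
})

test_that("prior slices integrate to finite mass", {
  pr <- prior_config(mu_y = 0.44, sigma_y = 1.09)
  p <- random_params(1, seed = 8)
  slice <- function(sig) {
    vapply(sig, function(s) {
      ps <- p; ps$sigma <- s
      exp(log_prior(ps, pr) - log_prior(p, pr))
    }, numeric(1))
  }
  mass <- integrate(slice, 1e-6, 20)$value
  expect_true(is.finite(mass) && mass > 0)
})

test_that("log posterior is likelihood plus prior and propagates -Inf", {
  an <- small_analytic(400)
  de <- encode_design(an)
  pr <- prior_config(y = de$y)
  for (m in 1:2) {
    p <- random_params(m, seed = 9)
    expect_equal(log_posterior(p, de$y, de, pr),
                 log_likelihood(p, de$y, de) + log_prior(p, pr))
  }
  pbad <- random_params(1, seed = 9)
  pbad$sd_edu <- -1
  expect_identical(log_posterior(pbad, de$y, de, pr), -Inf)
})

test_that("compiled posterior agrees with the plain-R composition", {
  an <- small_analytic(400)
  de <- encode_design(an)
  pr <- prior_config(y = de$y)
  for (m in 1:2) {
    set.seed(m + 20)
    th <- rnorm(if (m == 1) 33 else 63, 0, 0.4)
    expect_equal(gradient(th, de$y, de, pr, m)$lp,
                 crpdist:::log_posterior_unconstrained(th, de$y, de, pr, m),
                 tolerance = 1e-8)
  }
})

test_that("analytic gradients match central finite differences", {
  an <- small_analytic(400)
  de <- encode_design(an)
  pr <- prior_config(y = de$y)
  for (m in 1:2) {
    for (seed in 1:2) {
      set.seed(100 * m + seed)
      n_par <- if (m == 1) 33 else 63
      th <- rnorm(n_par, 0, 0.3)
      g <- gradient(th, de$y, de, pr, m)$grad
      h <- 1e-5
      fd <- vapply(seq_len(n_par), function(i) {
        tp <- th; tp[i] <- tp[i] + h
        tm <- th; tm[i] <- tm[i] - h
        (gradient(tp, de$y, de, pr, m)$lp -
           gradient(tm, de$y, de, pr, m)$lp) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(g - fd) / pmax(abs(fd), 1)), 1e-5)
    }
  }
})

test_that("prior-only gradient vanishes at the fixed-effect mode", {
  de <- toy_design()
  pr <- prior_config(y = de$y)
  # at beta_j = 0 the N(0,1) prior contributes zero gradient; with y absent
  # from the design columns (all-zero X) the likelihood term through X'dmu
  # is the only other contribution and vanishes too
  th <- rep(0, 33)
  th[32] <- log(1)      # sigma = 1
  th[33] <- log(29)     # nu = 30
  g <- gradient(th, de$y, de, pr, 1)$grad
  expect_equal(g[2:14], rep(0, 13), tolerance = 1e-12)
})

test_that("parameter packing round-trips through the unconstrained scale", {
  pr <- prior_config(mu_y = 0.4, sigma_y = 1.1)
  for (m in 1:2) {
    p <- random_params(m, seed = 11)
    th <- crpdist:::pack_params(p, pr, m)
    p2 <- crpdist:::unpack_params(th, pr, m)
    expect_equal(p2, p, tolerance = 1e-12)
    cons <- crpdist:::constrain_theta(th, pr, m)
    expect_equal(cons[["nu"]], p$nu, tolerance = 1e-12)
    expect_equal(length(cons), length(crpdist:::constrained_names(m)))
  }
})
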