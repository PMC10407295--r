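# Exclusion cascade, transforms, design encoding, descriptives.

test_that("BMI follows weight/(height/100)^2 with guards", {
  expect_equal(compute_bmi(100, 100), 100)
  expect_equal(compute_bmi(70, 175), 70 / 1.75^2)
  expect_true(is.na(compute_bmi(70, 0)))
  expect_true(is.na(compute_bmi(-1, 170)))
  expect_true(is.na(compute_bmi(NA, 170)))
})

test_that("log-CRP and the 3 mg/L risk cutoff use a strict inequality", {
  expect_equal(log_crp(1)$y, 0)
  expect_false(log_crp(1)$high_risk)
  lc3 <- log_crp(3)
  expect_equal(lc3$y, log(3), tolerance = 1e-12)
  expect_false(lc3$high_risk)   # strictly greater than 3
  lce <- log_crp(exp(3))
  expect_equal(lce$y, 3)
  expect_true(lce$high_risk)
  expect_true(is.na(log_crp(0)$y))
  expect_true(is.na(log_crp(-2)$y))
})

test_that("income equivalization follows the OECD scales", {
  expect_equal(equivalize_income(1000, 1, 0), 1000)
  expect_equal(equivalize_income(1500, 2, 0), 1000)
  expect_equal(equivalize_income(1800, 2, 1), 1000)
  # Oxford (original) scale: 1.0 / 0.7 / 0.5
  expect_equal(equivalize_income(1700, 2, 0, scale = "original"), 1000)
  expect_equal(equivalize_income(2200, 2, 1, scale = "original"), 1000)
  expect_error(equivalize_income(1000, 0, 0), "n_adults")
})

test_that("z-standardization centres and scales exactly", {
  expect_equal(as.numeric(zstandardize(c(1, 2, 3))), c(-1, 0, 1))
  for (seed in 1:3) {
    set.seed(seed)
    z <- zstandardize(rlnorm(100))
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sd(z) - 1), 1e-10)
  }
  expect_error(zstandardize(rep(2, 10)), "constant")
})

test_that("exclusion cascade counts every row once, in the stated order", {
  raw <- generate_dataset(generator_config(n = 300, seed = 8))
  ex <- apply_exclusions(raw)
  expect_equal(ex$log$rows_out, 300)
  expect_equal(ex$log$crp_missing + ex$log$bmi_inapplicable +
                 ex$log$crp_nonpositive + ex$log$covariate_missing, 0)

  # a CRP of zero is excluded under the non-positive-CRP reason
  raw1 <- raw
  raw1$crp[1] <- 0
  ex1 <- apply_exclusions(raw1)
  expect_equal(ex1$log$crp_nonpositive, 1)
  expect_equal(ex1$log$rows_out, 299)

  # first matching reason wins: CRP-missing trumps a missing covariate
  raw2 <- raw
  raw2$crp[1] <- NA
  raw2$income[1] <- NA
  ex2 <- apply_exclusions(raw2)
  expect_equal(ex2$log$crp_missing, 1)
  expect_equal(ex2$log$covariate_missing, 0)
})

test_that("exclusion conservation and idempotence hold under random missingness", {
  for (seed in 1:5) {
    raw <- generate_dataset(generator_config(n = 400, seed = seed))
    set.seed(seed + 50)
    raw$crp[sample(400, 20)] <- NA
    raw$height_cm[sample(400, 15)] <- NA
    raw$income[sample(400, 10)] <- NA
    raw$crp[sample(400, 5)] <- -abs(rnorm(5))
    ex <- apply_exclusions(raw)
    with(ex$log, expect_equal(
      rows_out + crp_missing + bmi_inapplicable + crp_nonpositive +
        covariate_missing, rows_in))
    ex2 <- apply_exclusions(ex$data)
    expect_equal(nrow(ex2$data), nrow(ex$data))
    expect_equal(ex2$log$rows_out, ex2$log$rows_in)
  }
})

test_that("analytic table is complete with exact z-invariants", {
  an <- small_analytic(400)
  expect_false(anyNA(an))
  for (col in c("z_sport", "z_age", "z_income", "z_bmi")) {
    expect_lt(abs(mean(an[[col]])), 1e-10)
    expect_lt(abs(sd(an[[col]]) - 1), 1e-10)
  }
  expect_true(all(exp(an$y) > 0))
})

test_that("design encoding uses reference categories and group indices", {
  an <- small_analytic(400)
  de <- encode_design(an)
  expect_equal(ncol(de$X), 13)
  expect_equal(colnames(de$X)[1:3], c("Gender (Female)", "Rent", "Other"))
  # gender dummy against male reference
  expect_equal(as.numeric(de$X[, "Gender (Female)"]),
               as.numeric(an$gender == "Female"))
  # 5-level self-rated health yields 4 dummies
  expect_equal(sum(colnames(de$X) %in% c("Very good", "Good", "Fair", "Poor")), 4)
  expect_true(all(de$X[, 1:9] %in% c(0, 1)))
  expect_true(all(de$edu %in% 1:6))
  expect_true(all(de$occ %in% 1:9))
  # continuous columns appended in the order sport, age, income, BMI
  expect_equal(colnames(de$X)[10:13],
               c("Sport Activity", "Age", "Income", "BMI"))
  bad <- an
  levels(bad$smoking) <- c(levels(bad$smoking), "Vaper")
  bad$smoking[1] <- "Vaper"
  expect_error(encode_design(bad), "unseen category")
})

test_that("descriptives report moments, proportions and mixed correlations", {
  an <- small_analytic(400)
  d <- descriptives(an)
  expect_equal(d$correlation["y", "y"], 1)
  expect_equal(unname(as.matrix(d$correlation)),
               unname(t(as.matrix(d$correlation))), tolerance = 1e-12)
  props <- d$summary[d$summary$variable == "gender", "mean"]
  expect_equal(sum(props), 1)
  # constant column reports SD 0
  an2 <- an
  an2$age <- 50
  expect_equal(descriptives(an2)$summary[
    descriptives(an2)$summary$variable == "age", "sd"], 0)
})

test_that("log-CRP/BMI correlation matches the published magnitude under generating truth", {
  cfg <- generator_config(n = 1e5, truth = published_truth(1), seed = 21)
  cov <- generate_covariates(cfg)
  y <- generate_response(cov, published_truth(1), seed = 22)
  bmi <- compute_bmi(cov$weight_kg, cov$height_cm)
  expect_lt(abs(cor(y, bmi) - 0.37), 0.05)
})
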