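# Complete-case preparation: exclusions, BMI, log-CRP, OECD equivalization,
# z-standardization, design encoding, descriptives.

covariate_columns <- function() {
  c("occupation", "education", "gender", "house", "srh", "smoking",
    "sport", "age", "income", "n_adults", "n_children")
}

#' Body mass index
#'
#' @param weight_kg weight in kilograms.
#' @param height_cm height in centimetres.
#' @return \code{weight/(height/100)^2}; non-positive or missing inputs give
#'   \code{NA}.
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  bmi <- weight_kg / (height_cm / 100)^2
  bmi[!is.finite(bmi) | weight_kg <= 0 | height_cm <= 0] <- NA_real_
  bmi
}

#' Log-transform CRP and flag low-grade inflammation
#'
#' @param crp CRP concentration in mg/L.
#' @return list with \code{y} (natural log of CRP) and \code{high_risk}
#'   (\code{crp > 3} mg/L, the low-grade inflammation cutoff; strict
#'   inequality). Non-positive CRP gives \code{NA} in both.
#' @export
log_crp <- function(crp) {
  bad <- !is.finite(crp) | crp <= 0
  y <- suppressWarnings(log(crp))
  y[bad] <- NA_real_
  hr <- crp > 3
  hr[bad] <- NA
  list(y = y, high_risk = hr)
}

#' OECD income equivalization
#'
#' Divides gross household income by an OECD equivalence factor reflecting
#' household composition. The default is the OECD-modified scale (first
#' adult 1.0, further adults 0.5, children 0.3); \code{"original"} selects
#' the Oxford scale (1.0/0.7/0.5).
#'
#' @param income gross household income.
#' @param n_adults number of adults (>= 1).
#' @param n_children number of children (under 14).
#' @param scale \code{"modified"} or \code{"original"}.
#' @return equivalized income.
#' @export
equivalize_income <- function(income, n_adults, n_children,
                              scale = c("modified", "original")) {
  scale <- match.arg(scale)
  if (any(n_adults < 1, na.rm = TRUE)) stop("n_adults must be at least 1")
  w <- if (scale == "modified") c(0.5, 0.3) else c(0.7, 0.5)
  income / (1 + w[1] * (n_adults - 1) + w[2] * n_children)
}

#' z-standardize a column
#'
#' Centers and scales by the sample mean and SD (n-1 denominator) of the
#' supplied values, i.e. the moments of the post-exclusion analytic sample.
#'
#' @param x numeric vector with at least two distinct values.
#' @return z-scores, with \code{center}/\code{scale} attributes.
#' @export
zstandardize <- function(x) {
  if (length(unique(x)) < 2) stop("cannot z-standardize a constant column")
  m <- mean(x)
  s <- stats::sd(x)
  structure((x - m) / s, center = m, scale = s)
}

#' Apply the study's exclusion cascade
#'
#' Drops rows in a fixed order, each row counted once under the first
#' matching reason: (1) CRP missing; (2) height/weight inapplicable, so BMI
#' cannot be computed; (3) CRP non-positive; (4) any remaining covariate
#' missing.
#'
#' @param raw raw-table data.frame.
#' @return list with \code{data} (surviving rows) and \code{log}, an
#'   exclusion log with per-reason counts satisfying
#'   \code{rows_out + sum(counts) == rows_in}.
#' @export
apply_exclusions <- function(raw) {
  n_in <- nrow(raw)
  crp_missing <- is.na(raw$crp)
  bmi_na <- is.na(compute_bmi(raw$weight_kg, raw$height_cm))
  crp_nonpos <- !crp_missing & raw$crp <= 0
  cov_missing <- Reduce(`|`, lapply(raw[covariate_columns()], is.na))

  reason <- rep(NA_character_, n_in)
  reason[cov_missing] <- "covariate_missing"
  reason[crp_nonpos] <- "crp_nonpositive"
  reason[bmi_na] <- "bmi_inapplicable"
  reason[crp_missing] <- "crp_missing"

  keep <- is.na(reason)
  log <- list(
    rows_in = n_in,
    rows_out = sum(keep),
    crp_missing = sum(reason == "crp_missing", na.rm = TRUE),
    bmi_inapplicable = sum(reason == "bmi_inapplicable", na.rm = TRUE),
    crp_nonpositive = sum(reason == "crp_nonpositive", na.rm = TRUE),
    covariate_missing = sum(reason == "covariate_missing", na.rm = TRUE)
  )
  if (log$rows_out == 0) {
    stop("no rows survive the exclusions (in: ", n_in,
         "; crp_missing: ", log$crp_missing,
         ", bmi_inapplicable: ", log$bmi_inapplicable,
         ", crp_nonpositive: ", log$crp_nonpositive,
         ", covariate_missing: ", log$covariate_missing, ")")
  }
  list(data = raw[keep, , drop = FALSE], log = log)
}

#' Build the analytic table from complete raw rows
#'
#' Computes BMI, log-CRP and the high-risk flag, equivalizes income, and
#' z-standardizes sport activity, age, equivalized income and BMI on the
#' supplied (post-exclusion) sample.
#'
#' @param raw complete raw rows (run [apply_exclusions()] first).
#' @param oecd_scale equivalence scale, see [equivalize_income()].
#' @param require_crp if \code{FALSE}, the CRP column may be absent/missing
#'   (used when encoding covariates for response generation).
#' @return analytic data.frame with raw and z-scored covariates.
#' @export
prepare_analytic <- function(raw, oecd_scale = "modified", require_crp = TRUE) {
  bmi <- compute_bmi(raw$weight_kg, raw$height_cm)
  inc <- equivalize_income(raw$income, raw$n_adults, raw$n_children,
                           scale = oecd_scale)
  out <- data.frame(
    occupation = raw$occupation, education = raw$education,
    gender = raw$gender, house = raw$house, srh = raw$srh,
    smoking = raw$smoking,
    sport = raw$sport, age = raw$age, income = inc, bmi = bmi
  )
  if (require_crp) {
    lc <- log_crp(raw$crp)
    out$y <- lc$y
    out$high_risk <- lc$high_risk
  }
  if (anyNA(out)) stop("analytic table has missing values; apply exclusions first")
  out$z_sport <- zstandardize(out$sport)
  out$z_age <- zstandardize(out$age)
  out$z_income <- zstandardize(out$income)
  out$z_bmi <- zstandardize(out$bmi)
  out
}

#' Encode the design matrices
#'
#' Dummy-codes gender (reference Male), house ownership (reference Owned),
#' self-rated health (reference Excellent) and smoking (reference Smoker),
#' appends the z-scored sport, age, income and BMI columns, and returns
#' education and occupation as group indices for the hierarchical deviations.
#'
#' @param analytic analytic table from [prepare_analytic()].
#' @return list with the fixed-effect matrix \code{X}, integer group indices
#'   \code{edu}/\code{occ}, the response \code{y} (if present) and a
#'   reference-category registry.
#' @export
encode_design <- function(analytic) {
  m <- default_marginals()
  check_levels <- function(x, v) {
    lv <- m[[v]]$levels
    if (!all(as.character(x) %in% lv)) {
      stop("unseen category in ", v, ": ",
           paste(setdiff(unique(as.character(x)), lv), collapse = ", "))
    }
    factor(as.character(x), levels = lv)
  }
  gender <- check_levels(analytic$gender, "gender")
  house <- check_levels(analytic$house, "house")
  srh <- check_levels(analytic$srh, "srh")
  smoking <- check_levels(analytic$smoking, "smoking")
  edu <- check_levels(analytic$education, "education")
  occ <- check_levels(analytic$occupation, "occupation")

  dummies <- function(f) {
    lv <- levels(f)[-1]
    sapply(lv, function(l) as.numeric(f == l))
  }
  X <- cbind(dummies(gender), dummies(house), dummies(srh), dummies(smoking),
             analytic$z_sport, analytic$z_age, analytic$z_income,
             analytic$z_bmi)
  colnames(X) <- fixed_effect_names()
  list(
    X = X,
    edu = as.integer(edu),
    occ = as.integer(occ),
    y = analytic$y,
    n = nrow(X),
    references = c(gender = "Male", house = "Owned", srh = "Excellent",
                   smoking = "Smoker"),
    edu_levels = levels(edu),
    occ_levels = levels(occ)
  )
}

#' Descriptive statistics of the analytic sample
#'
#' Means/SDs for continuous measures, category proportions, and a pairwise
#' correlation matrix (product-moment between continuous variables;
#' rank-based when a categorical's integer codes are involved).
#'
#' @param analytic analytic table.
#' @return list with \code{summary} and \code{correlation} data frames.
#' @export
descriptives <- function(analytic) {
  cont <- c("y", "sport", "age", "income", "bmi")
  cats <- c("occupation", "education", "gender", "house", "srh", "smoking")
  rows <- lapply(cont, function(v) {
    data.frame(variable = v, level = NA_character_,
               mean = mean(analytic[[v]]), sd = stats::sd(analytic[[v]]))
  })
  for (v in cats) {
    p <- prop.table(table(analytic[[v]]))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = names(p), mean = as.numeric(p),
      sd = sqrt(as.numeric(p) * (1 - as.numeric(p))))
  }
  summary_tab <- do.call(rbind, rows)

  vars <- c("y", cats, "sport", "age", "income", "bmi")
  is_cat <- vars %in% cats
  M <- sapply(vars, function(v) as.numeric(analytic[[v]]))
  k <- length(vars)
  C <- diag(k)
  dimnames(C) <- list(vars, vars)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      method <- if (is_cat[i] || is_cat[j]) "spearman" else "pearson"
      C[i, j] <- C[j, i] <- if (stats::sd(M[, i]) == 0 || stats::sd(M[, j]) == 0) {
        NA_real_   # constant column: correlation undefined
      } else {
        stats::cor(M[, i], M[, j], method = method)
      }
    }
  }
  list(summary = summary_tab, correlation = as.data.frame(C))
}
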