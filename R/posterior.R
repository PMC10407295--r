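# Paper-facing posterior outputs: summary tables, contrasts, density
# intervals, sampled regression lines.

pooled_draws <- function(x, parameter = NULL) {
  if (inherits(x, "crp_fit")) x <- x$chains
  if (inherits(x, "crp_chains")) {
    if (is.null(parameter)) {
      d <- x$draws
      out <- matrix(d, nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3])
      colnames(out) <- dimnames(d)[[3]]
      return(out)
    }
    return(as.numeric(x$draws[, , parameter]))
  }
  x
}

# section labels for the reporting layout of the published tables
parameter_section <- function(names) {
  sec <- rep("Fixed effects", length(names))
  sec[names %in% c("Intercept", "sigma_Intercept")] <- "Intercept"
  sec[grepl("^Education: ", names)] <- "Education, Intercepts"
  sec[grepl("^Occupation: ", names)] <- "Occupation, Intercepts"
  sec[grepl("^sigma_Education: ", names)] <- "sigma Education, Intercepts"
  sec[grepl("^sigma_Occupation: ", names)] <- "sigma Occupation, Intercepts"
  sec[grepl("Std (Education|Occupation)", names)] <- "Group SDs"
  sec[names %in% c("sigma", "nu")] <- "Distribution"
  sec
}

#' Posterior summary table
#'
#' Pooled cross-chain posterior mean, SD and 2.5/50/97.5\% quantiles per
#' parameter, ordered and labelled like the published regression tables.
#' Quantiles use the median-unbiased estimator (type 8).
#'
#' @param x a \code{crp_fit} or \code{crp_chains}.
#' @return data.frame of class \code{crp_summary} with columns
#'   \code{parameter, section, mean, sd, q2.5, q50, q97.5}.
#' @export
posterior_summary <- function(x) {
  draws <- pooled_draws(x)
  qs <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                type = 8, names = FALSE))
  out <- data.frame(
    parameter = colnames(draws),
    section = parameter_section(colnames(draws)),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3],
    row.names = NULL
  )
  class(out) <- c("crp_summary", "data.frame")
  out
}

#' @export
print.crp_summary <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}

#' Posterior contrasts against a reference category
#'
#' Per-draw differences between each category's group deviation and the
#' reference category's deviation, for the location side (both models) or
#' the log-scale side (Model 2).
#'
#' @param x a \code{crp_fit} or \code{crp_chains}.
#' @param factor \code{"education"} or \code{"occupation"}.
#' @param reference reference category label; defaults to the first level
#'   (highest status category).
#' @param side \code{"mu"} or \code{"sigma"}.
#' @return a \code{crp_contrasts} object: draws matrix (one column per
#'   category, reference column identically 0) plus labels.
#' @export
crp_contrasts <- function(x, factor = c("education", "occupation"),
                          reference = NULL, side = c("mu", "sigma")) {
  factor <- match.arg(factor)
  side <- match.arg(side)
  levels <- if (factor == "education") education_levels() else occupation_levels()
  if (is.null(reference)) reference <- levels[1]
  if (!reference %in% levels) stop("unknown reference category: ", reference)
  prefix <- if (side == "mu") "" else "sigma_"
  label <- if (factor == "education") "Education: " else "Occupation: "
  cols <- paste0(prefix, label, levels)
  draws <- pooled_draws(x)
  if (!all(cols %in% colnames(draws))) {
    stop("requested deviations not present in the draws (side = ", side, ")")
  }
  dev <- draws[, cols, drop = FALSE]
  contrast <- dev - dev[, paste0(prefix, label, reference)]
  colnames(contrast) <- levels
  structure(list(draws = contrast, reference = reference,
                 factor = factor, side = side),
            class = "crp_contrasts")
}

#' @export
print.crp_contrasts <- function(x, ...) {
  cat("Posterior contrasts (", x$factor, ", ", x$side,
      " side) vs reference: ", x$reference, "\n", sep = "")
  s <- data.frame(
    category = colnames(x$draws),
    mean = colMeans(x$draws),
    low65 = apply(x$draws, 2, function(v) density_interval(v, 0.65)[1]),
    high65 = apply(x$draws, 2, function(v) density_interval(v, 0.65)[2]),
    row.names = NULL
  )
  s[-1] <- lapply(s[-1], round, 3)
  print.data.frame(s, row.names = FALSE, ...)
  invisible(x)
}

#' Posterior density interval
#'
#' Central (equal-tail) interval containing \code{mass} of the draws by
#' default, as used for the thick 65\% bars under the posterior density
#' plots; \code{method = "hpd"} gives the narrowest interval instead.
#'
#' @param draws numeric vector of posterior draws.
#' @param mass probability mass (default 0.65).
#' @param method \code{"central"} or \code{"hpd"}.
#' @return numeric \code{c(low, high)}.
#' @export
density_interval <- function(draws, mass = 0.65,
                             method = c("central", "hpd")) {
  method <- match.arg(method)
  stopifnot(mass > 0, mass <= 1)
  if (mass == 1) return(range(draws))
  if (method == "central") {
    a <- (1 - mass) / 2
    as.numeric(stats::quantile(draws, c(a, 1 - a), type = 8, names = FALSE))
  } else {
    s <- sort(draws)
    n <- length(s)
    k <- max(1, ceiling(mass * n))
    widths <- s[k:n] - s[seq_len(n - k + 1)]
    i <- which.min(widths)
    c(s[i], s[i + k - 1])
  }
}

#' Sample regression lines from the posterior
#'
#' Draws \code{k} (intercept, slope) pairs without replacement from the
#' pooled post-warmup draws, reproducing the "20 possible regression lines"
#' income plots; \code{side = "sigma"} uses the log-scale intercept and
#' slope (Model 2).
#'
#' @param x a \code{crp_fit} or \code{crp_chains}.
#' @param predictor fixed-effect name (default \code{"Income"}).
#' @param k number of lines.
#' @param seed integer seed.
#' @param side \code{"mu"} or \code{"sigma"}.
#' @return data.frame with columns \code{intercept} and \code{slope}.
#' @export
sample_regression_lines <- function(x, predictor = "Income", k = 20,
                                    seed = 1, side = c("mu", "sigma")) {
  side <- match.arg(side)
  prefix <- if (side == "mu") "" else "sigma_"
  draws <- pooled_draws(x)
  icol <- paste0(prefix, "Intercept")
  scol <- paste0(prefix, predictor)
  if (!all(c(icol, scol) %in% colnames(draws))) {
    stop("predictor ", scol, " not present in the draws")
  }
  n <- nrow(draws)
  if (k > n) stop("k exceeds the number of pooled draws")
  set.seed(as.integer(seed))
  idx <- sample.int(n, k)
  data.frame(intercept = draws[idx, icol], slope = draws[idx, scol])
}
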