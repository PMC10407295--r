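# Convergence diagnostics: split R-hat, effective sample size,
# autocorrelation.

# Accepts a crp_chains/crp_fit plus parameter name, or a draws matrix
# (iterations x chains).
draws_matrix <- function(x, parameter = NULL) {
  if (inherits(x, "crp_fit")) x <- x$chains
  if (inherits(x, "crp_chains")) {
    if (is.null(parameter)) stop("parameter name required")
    return(x$draws[, , parameter])
  }
  as.matrix(x)
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half; R-hat compares within- and between-chain
#' variance across the split chains. Values near 1 indicate convergence.
#'
#' @param x a \code{crp_fit}, \code{crp_chains}, or an iterations-by-chains
#'   matrix of draws.
#' @param parameter parameter name when \code{x} is a fit/chain set.
#' @return R-hat, or \code{NA} (with attribute \code{undefined = TRUE}) for
#'   zero-variance chains.
#' @export
rhat <- function(x, parameter = NULL) {
  m <- draws_matrix(x, parameter)
  n <- nrow(m)
  if (n < 4 || ncol(m) < 2) stop("need at least 2 chains of 4 draws")
  half <- floor(n / 2)
  split <- cbind(m[seq_len(half), , drop = FALSE],
                 m[(n - half + 1):n, , drop = FALSE])
  W <- mean(apply(split, 2, stats::var))
  if (!is.finite(W) || W == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  B_over_n <- stats::var(colMeans(split))
  var_plus <- (half - 1) / half * W + B_over_n
  sqrt(var_plus / W)
}

#' Per-lag autocorrelation of posterior draws
#'
#' Average of per-chain autocorrelation estimates.
#'
#' @inheritParams rhat
#' @param max_lag largest lag.
#' @return numeric vector of length \code{max_lag + 1} (lag 0 first).
#' @export
autocorrelation <- function(x, parameter = NULL, max_lag = 50) {
  m <- draws_matrix(x, parameter)
  max_lag <- min(max_lag, nrow(m) - 1)
  per_chain <- apply(m, 2, function(v) {
    if (stats::sd(v) == 0) return(rep(NA_real_, max_lag + 1))
    drop(stats::acf(v, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf)
  })
  rowMeans(as.matrix(per_chain))
}

#' Effective sample size
#'
#' Autocorrelation-based ESS: combined per-chain autocovariances feed the
#' usual between/within variance estimate, and the autocorrelation sum is
#' truncated by Geyer's initial positive-pair rule with a monotone cap.
#'
#' @inheritParams rhat
#' @return effective sample size, or \code{NA} for zero-variance chains.
#' @export
ess <- function(x, parameter = NULL) {
  m <- draws_matrix(x, parameter)
  n <- nrow(m); n_chain <- ncol(m)
  W <- mean(apply(m, 2, stats::var))
  if (!is.finite(W) || W == 0) return(structure(NA_real_, undefined = TRUE))
  B_over_n <- if (n_chain > 1) stats::var(colMeans(m)) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  max_lag <- n - 1
  acov <- apply(m, 2, function(v) {
    drop(stats::acf(v, lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf)
  })
  mean_acov <- rowMeans(as.matrix(acov))
  rho <- 1 - (W - mean_acov) / var_plus   # rho[1] is lag 0
  # Geyer initial monotone positive sequence over consecutive pairs
  max_pairs <- floor((length(rho) - 1) / 2)
  s <- 0
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    s <- s + pair
    prev <- pair
  }
  n_chain * n / (1 + 2 * s)
}
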