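# Hamiltonian Monte Carlo with dual-averaging step-size adaptation and
# diagonal mass-matrix estimation during warmup.

#' Sampler configuration
#'
#' Defaults follow the study protocol: 4 chains of 2000 iterations, the
#' first 1000 discarded; the discarded half doubles as the adaptation window
#' (dual-averaging step size targeting \code{target_accept}, diagonal mass
#' matrix re-estimated mid-warmup). Trajectories use a leapfrog step count
#' jittered uniformly on \code{1:max_leapfrog}.
#'
#' @param n_chains number of chains.
#' @param n_iterations total iterations per chain.
#' @param n_warmup warmup (burn-in) iterations, discarded.
#' @param target_accept dual-averaging acceptance target.
#' @param max_leapfrog maximum leapfrog steps per transition.
#' @param init_range chains start from unconstrained coordinates drawn
#'   uniformly on \code{[-init_range, init_range]}. The default of 1 keeps
#'   the scale-side linear predictor of the distributional model within a
#'   sane range at initialization; wide jitter can strand a chain in the
#'   heavy-tail region where adaptation collapses.
#' @return a \code{sampler_control} list.
#' @export
sampler_control <- function(n_chains = 4, n_iterations = 2000,
                            n_warmup = 1000, target_accept = 0.8,
                            max_leapfrog = 32, init_range = 1) {
  stopifnot(n_chains >= 1, n_warmup < n_iterations, n_warmup >= 20,
            target_accept > 0, target_accept < 1, max_leapfrog >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup),
                 target_accept = target_accept,
                 max_leapfrog = as.integer(max_leapfrog),
                 init_range = init_range),
            class = "sampler_control")
}

#' Initialize a chain
#'
#' Draws unconstrained coordinates uniformly on
#' \code{[-init_range, init_range]}, redrawing (up to 100 times) until the
#' log posterior is finite. Deterministic given seed and chain index.
#'
#' @param target sampling target (see [make_target()]).
#' @param control a [sampler_control()].
#' @param seed master seed.
#' @param chain chain index.
#' @return unconstrained initial position.
#' @export
initialize_chain <- function(target, control, seed, chain = 1) {
  set.seed(chain_seed(seed, chain))
  for (attempt in seq_len(100)) {
    q <- stats::runif(target$n_par, -control$init_range, control$init_range)
    if (is.finite(target$lp(q))) return(q)
  }
  stop("could not find a finite starting point in 100 attempts")
}

# fixed per-chain offset from the master seed, kept within 32-bit range
chain_seed <- function(seed, chain) {
  (as.integer(seed) + 7919L * as.integer(chain)) %% .Machine$integer.max
}

# one leapfrog trajectory; target$grad returns list(lp, grad)
leapfrog <- function(target, q, p, grad, eps, L, Minv) {
  p <- p + 0.5 * eps * grad
  gl <- NULL
  for (l in seq_len(L)) {
    q <- q + eps * Minv * p
    gl <- target$grad(q)
    if (!is.finite(gl$lp) || any(!is.finite(gl$grad))) {
      return(list(ok = FALSE))
    }
    if (l < L) p <- p + eps * gl$grad
  }
  p <- p + 0.5 * eps * gl$grad
  list(ok = TRUE, q = q, p = p, lp = gl$lp, grad = gl$grad)
}

# doubling/halving heuristic for a sane initial step size
find_epsilon <- function(target, q, grad, lp, Minv, sqrt_mass) {
  eps <- 0.1
  p <- stats::rnorm(length(q)) * sqrt_mass
  H0 <- -lp + 0.5 * sum(p^2 * Minv)
  step_dH <- function(eps) {
    out <- leapfrog(target, q, p, grad, eps, 1L, Minv)
    if (!out$ok) return(-Inf)
    H0 - (-out$lp + 0.5 * sum(out$p^2 * Minv))
  }
  dH <- step_dH(eps)
  dir <- if (is.finite(dH) && dH > log(0.5)) 1 else -1
  for (i in seq_len(50)) {
    eps <- eps * 2^dir
    dH <- step_dH(eps)
    if (dir == 1 && !(is.finite(dH) && dH > log(0.5))) break
    if (dir == -1 && (is.finite(dH) && dH > log(0.5))) break
  }
  max(min(eps, 10), 1e-8)
}

run_single_chain <- function(target, control, seed, chain) {
  q <- initialize_chain(target, control, seed, chain)
  n_par <- target$n_par
  W <- control$n_warmup
  n_iter <- control$n_iterations
  n_keep <- n_iter - W

  gl <- target$grad(q)
  lp <- gl$lp; grad <- gl$grad
  Minv <- rep(1, n_par)
  sqrt_mass <- rep(1, n_par)

  eps <- find_epsilon(target, q, grad, lp, Minv, sqrt_mass)
  # dual-averaging state (Hoffman-Gelman constants)
  da_gamma <- 0.05; da_t0 <- 10; da_kappa <- 0.75
  da_reset <- function(eps) list(mu = log(10 * eps), Hbar = 0,
                                 log_eps_bar = log(eps), cnt = 0)
  da <- da_reset(eps)

  # expanding covariance-estimation windows: the diagonal mass matrix is
  # re-estimated at the end of each window (window sizes doubling), the step
  # size re-found and dual averaging restarted, so chains recover from a bad
  # early region of the warmup
  init_buffer <- min(75, floor(W * 0.15))
  term_buffer <- min(150, floor(W * 0.15))
  window_ends <- integer(0)
  wsize <- 25
  pos <- init_buffer
  while (pos + wsize <= W - term_buffer) {
    if (pos + 3 * wsize > W - term_buffer) wsize <- (W - term_buffer) - pos
    pos <- pos + wsize
    window_ends <- c(window_ends, pos)
    wsize <- 2 * wsize
  }
  window_starts <- c(init_buffer, utils::head(window_ends, -1)) + 1L
  warm_buf <- if (W > 0) matrix(NA_real_, W, n_par) else NULL

  keep <- matrix(NA_real_, n_keep, n_par)
  n_accept <- 0L
  n_divergent <- 0L

  for (t in seq_len(n_iter)) {
    L <- sample.int(control$max_leapfrog, 1L)
    p0 <- stats::rnorm(n_par) * sqrt_mass
    H0 <- -lp + 0.5 * sum(p0^2 * Minv)
    out <- leapfrog(target, q, p0, grad, eps, L, Minv)
    if (out$ok) {
      H1 <- -out$lp + 0.5 * sum(out$p^2 * Minv)
      dH <- H0 - H1
      divergent <- !is.finite(dH) || dH < -1000
    } else {
      dH <- -Inf
      divergent <- TRUE
    }
    alpha <- if (is.finite(dH)) min(1, exp(dH)) else 0
    if (!divergent && stats::runif(1) < alpha) {
      q <- out$q; lp <- out$lp; grad <- out$grad
      if (t > W) n_accept <- n_accept + 1L
    }
    if (t <= W) {
      warm_buf[t, ] <- q
      da$cnt <- da$cnt + 1
      frac <- 1 / (da$cnt + da_t0)
      da$Hbar <- (1 - frac) * da$Hbar + frac * (control$target_accept - alpha)
      log_eps <- da$mu - sqrt(da$cnt) / da_gamma * da$Hbar
      eta <- da$cnt^(-da_kappa)
      da$log_eps_bar <- eta * log_eps + (1 - eta) * da$log_eps_bar
      eps <- max(min(exp(log_eps), 10), 1e-8)
      w <- match(t, window_ends)
      if (!is.na(w)) {
        from <- window_starts[w]
        v <- apply(warm_buf[from:t, , drop = FALSE], 2, stats::var)
        nw <- t - from + 1
        v <- v * nw / (nw + 5) + 1e-3 * 5 / (nw + 5)
        v[!is.finite(v) | v <= 0] <- 1
        Minv <- v
        sqrt_mass <- 1 / sqrt(v)
        eps <- find_epsilon(target, q, grad, lp, Minv, sqrt_mass)
        da <- da_reset(eps)
      }
      if (t == W) eps <- max(min(exp(da$log_eps_bar), 10), 1e-8)
    } else {
      if (divergent) n_divergent <- n_divergent + 1L
      keep[t - W, ] <- q
    }
  }
  list(draws = keep, accept_rate = n_accept / n_keep,
       divergences = n_divergent, step_size = eps, mass_inv = Minv,
       seed = chain_seed(seed, chain))
}

#' Run HMC chains
#'
#' Static-path HMC with a uniformly jittered leapfrog step count. Step size
#' is tuned by dual averaging during warmup and a diagonal mass matrix is
#' estimated from mid-warmup draws; both are frozen afterwards. Chains are
#' deterministic given the master seed (per-chain seeds are derived by a
#' fixed offset). More than 10\% divergent post-warmup transitions raises a
#' warning flag on the result, not an error.
#'
#' @param target list with \code{lp(theta)}, \code{grad(theta)} (returning
#'   \code{list(lp, grad)}), \code{n_par}, and optionally \code{names} and
#'   \code{constrain} (a per-draw transform to the reporting scale).
#' @param control a [sampler_control()].
#' @param seed master seed.
#' @return a \code{crp_chains} object: post-warmup draws indexed
#'   (iteration, chain, parameter) on the reporting scale when the target
#'   supplies \code{constrain}, plus acceptance/divergence statistics and
#'   seed provenance.
#' @export
run_chains <- function(target, control = sampler_control(), seed = 1) {
  chains <- lapply(seq_len(control$n_chains), function(ch) {
    run_single_chain(target, control, seed, ch)
  })
  raw <- lapply(chains, `[[`, "draws")
  if (!is.null(target$constrain)) {
    draws_list <- lapply(raw, function(m) {
      t(apply(m, 1, target$constrain))
    })
    par_names <- names(target$constrain(raw[[1]][1, ]))
  } else {
    draws_list <- raw
    par_names <- if (!is.null(target$names)) target$names
                 else paste0("par", seq_len(ncol(raw[[1]])))
  }
  n_keep <- nrow(draws_list[[1]])
  n_par <- ncol(draws_list[[1]])
  arr <- array(NA_real_, dim = c(n_keep, control$n_chains, n_par),
               dimnames = list(NULL, paste0("chain", seq_len(control$n_chains)),
                               par_names))
  for (ch in seq_len(control$n_chains)) arr[, ch, ] <- draws_list[[ch]]
  if (any(!is.finite(arr))) stop("non-finite draws in chain output")
  divergences <- vapply(chains, `[[`, integer(1), "divergences")
  res <- structure(list(
    draws = arr,
    unconstrained = raw,
    accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
    divergences = divergences,
    step_size = vapply(chains, `[[`, numeric(1), "step_size"),
    chain_seeds = vapply(chains, `[[`, numeric(1), "seed"),
    seed = seed,
    control = control
  ), class = "crp_chains")
  res$divergence_warning <- sum(divergences) >
    0.1 * control$n_chains * n_keep
  if (res$divergence_warning) {
    warning("more than 10% divergent transitions after warmup")
  }
  res
}
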