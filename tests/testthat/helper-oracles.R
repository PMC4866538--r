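# Independent oracles used across the suite. Each is implemented from the
# defining formula or by brute force, deliberately avoiding the code paths
# it checks.

# Clopper-Pearson lower bound by bisection on the exact binomial tail:
# the largest p0 with P(X >= minor | n, p0) <= alpha/2.
oracle_cp_lower <- function(minor, depth, level = 0.9973, tol = 1e-15) {
  if (minor == 0) return(0)
  alpha <- 1 - level
  tail_ge <- function(p) sum(dbinom(minor:depth, depth, p))
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (tail_ge(mid) < alpha / 2) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# hypergeometric upper tail P(X >= s) from the defining ratio of binomial
# coefficients (not phyper)
oracle_hyper_upper <- function(N, S, n, s) {
  ks <- max(s, max(0, n - (N - S))):min(n, S)
  if (s > min(n, S)) return(0)
  sum(choose(S, ks) * choose(N - S, n - ks)) / choose(N, n)
}

# exact two-sided binomial p by summation over all outcomes with
# probability <= that of the observed outcome (minimum-likelihood rule)
oracle_binom_two_sided <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# diffStat by explicit enumeration of the nine treatment x control pairs
oracle_diffstat <- function(af, cf) {
  d <- as.vector(outer(af, cf, "-"))
  stopifnot(length(d) == length(af) * length(cf))
  if (all(d > 0) || all(d < 0)) min(abs(d)) else 0
}

# deterministic one-locus selection recursion (fitnesses 1, 1+hs, 1+s for
# genotypes aa, Aa, AA), iterated `gens` times
oracle_selection_recursion <- function(p, s, h, gens) {
  for (i in seq_len(gens)) {
    q <- 1 - p
    wbar <- p^2 * (1 + s) + 2 * p * q * (1 + h * s) + q^2
    p <- (p^2 * (1 + s) + p * q * (1 + h * s)) / wbar
  }
  p
}

# independent GLMM fit: marginal likelihood by dense fixed-grid
# integration over the random intercept, maximized with optim(), Wald p
# from a finite-difference Hessian
oracle_glmm_p <- function(alt, depth, treat, grid_hw = 8, grid_n = 3201) {
  u <- seq(-grid_hw, grid_hw, length.out = grid_n)
  du <- u[2] - u[1]
  nll <- function(par) {
    b0 <- par[1]; b1 <- par[2]; s <- abs(par[3])
    ll <- 0
    for (i in seq_along(alt)) {
      dens <- dbinom(alt[i], depth[i], plogis(b0 + b1 * treat[i] + u)) *
        dnorm(u, 0, max(s, 1e-8))
      ll <- ll + log(sum(dens) * du)
    }
    if (!is.finite(ll)) 1e10 else -ll
  }
  fit <- optim(c(0, 0, 0.3), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  fit <- optim(fit$par, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  # central-difference Hessian
  p <- fit$par
  hstep <- 1e-4 * (1 + abs(p))
  H <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    pp <- p; pp[i] <- pp[i] + hstep[i]; pp[j] <- pp[j] + hstep[j]
    fpp <- nll(pp)
    pp <- p; pp[i] <- pp[i] + hstep[i]; pp[j] <- pp[j] - hstep[j]
    fpm <- nll(pp)
    pp <- p; pp[i] <- pp[i] - hstep[i]; pp[j] <- pp[j] + hstep[j]
    fmp <- nll(pp)
    pp <- p; pp[i] <- pp[i] - hstep[i]; pp[j] <- pp[j] - hstep[j]
    fmm <- nll(pp)
    H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * hstep[i] * hstep[j])
  }
  se1 <- if (abs(p[3]) < 1e-4) {
    sqrt(solve(H[1:2, 1:2])[2, 2])
  } else {
    sqrt(solve(H)[2, 2])
  }
  z <- p[2] / se1
  list(beta1 = p[2], se1 = se1, p = 2 * pnorm(-abs(z)))
}

# small helper: simulated experiment with sensible test-scale defaults
quick_config <- function(...) {
  args <- modifyList(list(n_loci = 300, ne = 200, arms = c(chr2L = 1e6),
                          depth_mean = 60, unlinked = TRUE, seed = 42),
                     list(...))
  do.call(sim_config, args)
}
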