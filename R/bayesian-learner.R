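# Hierarchical Bayesian learner for a Bernoulli outcome stream whose
# underlying probability r drifts at a rate set by a latent log-volatility v,
# itself a random walk whose step variance is set by a volatility trend k.
# Inference is exact on a discretised (r, v, k) grid: each trial multiplies
# the joint posterior by the Bernoulli likelihood and then propagates it
# through the transition kernels
#   v' | v, k ~ Normal(v, exp(k))
#   r' | r, v' ~ Beta with mean r and concentration exp(-v')
# so that higher estimated volatility lets r move faster.

default_learner_grid <- function() {
  list(r = seq(0.01, 0.99, length.out = 50L),
       v = seq(-8, 2, length.out = 30L),
       k = seq(-4, 2, length.out = 15L))
}

# Transition kernel matrices, normalised over the destination state.
learner_kernels <- function(grid) {
  nr <- length(grid$r); nv <- length(grid$v); nk <- length(grid$k)
  # Tv[v, v', k]
  Tv <- array(NA_real_, c(nv, nv, nk))
  for (ik in seq_len(nk)) {
    sd_v <- sqrt(exp(grid$k[ik]))
    M <- outer(grid$v, grid$v, function(v0, v1) dnorm(v1, v0, sd_v))
    Tv[, , ik] <- M / rowSums(M)
  }
  # Tr[r, r', v']: beta drift with mean r and concentration exp(-v').
  Tr <- array(NA_real_, c(nr, nr, nv))
  for (iv in seq_len(nv)) {
    conc <- exp(-grid$v[iv])
    M <- outer(grid$r, grid$r, function(r0, r1) {
      dbeta(r1, 1e-6 + r0 * conc, 1e-6 + (1 - r0) * conc)
    })
    M[!is.finite(M)] <- 0
    rs <- rowSums(M)
    rs[rs == 0] <- 1
    Tr[, , iv] <- M / rs
  }
  list(Tv = Tv, Tr = Tr)
}

#' Bayesian volatility-tracking learner
#'
#' Filters a 0/1 outcome stream with a hierarchical Bayesian model in which
#' the outcome probability `r` drifts trial-to-trial at a rate governed by a
#' latent log-volatility, itself allowed to drift. The learner has no free
#' parameters; posterior inference runs on a fixed discretisation of the
#' latent state.
#'
#' @param out01 Numeric vector of 0/1 outcome indicators.
#' @param grid Optional list with numeric grids `r`, `v` (log-volatility) and
#'   `k` (log-volatility trend); defaults to a 50 x 30 x 15 grid.
#' @return List with `r_hat` (per-trial predictive mean of `r`, i.e. the
#'   belief entering each trial), `v_hat` (predictive mean log-volatility),
#'   `posterior` (final joint posterior array) and `grid`. Warns if the final
#'   posterior concentrates on the edges of the `r` or `v` grid.
#' @export
bayesian_learner <- function(out01, grid = default_learner_grid()) {
  stopifnot(all(out01 %in% c(0, 1)), length(out01) >= 1L)
  nr <- length(grid$r); nv <- length(grid$v); nk <- length(grid$k)
  kern <- learner_kernels(grid)
  # Pre-transpose the r-kernel per destination v' for the propagation step.
  TrT <- lapply(seq_len(nv), function(iv) t(kern$Tr[, , iv]))

  P <- array(1 / (nr * nv * nk), c(nr, nv, nk))
  n <- length(out01)
  r_hat <- numeric(n)
  v_hat <- numeric(n)
  marg_r <- function(P) apply(P, 1, sum)
  marg_v <- function(P) apply(P, 2, sum)

  for (i in seq_len(n)) {
    r_hat[i] <- sum(marg_r(P) * grid$r)
    v_hat[i] <- sum(marg_v(P) * grid$v)
    # Observation update.
    lik <- if (out01[i] == 1) grid$r else 1 - grid$r
    P <- P * lik
    P <- P / sum(P)
    # Propagation: v then r.
    A <- array(NA_real_, c(nr, nv, nk))              # A[r, v', k]
    for (ik in seq_len(nk)) A[, , ik] <- P[, , ik] %*% kern$Tv[, , ik]
    for (iv in seq_len(nv)) P[, iv, ] <- TrT[[iv]] %*% A[, iv, ]
    P <- P / sum(P)
  }
  mr <- marg_r(P); mv <- marg_v(P)
  if (mr[1] + mr[nr] > 0.5 || mv[1] + mv[nv] > 0.5) {
    warning("posterior mass concentrates on the grid edge; ",
            "consider widening the learner grid")
  }
  list(r_hat = r_hat, v_hat = v_hat, posterior = P, grid = grid)
}
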