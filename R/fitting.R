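#' Default parameter grids for grid-posterior fitting
#'
#' Learning rates use 50 equally spaced points on \[0.01, 0.99\]; inverse
#' temperatures 40 log-spaced points on \[0.1, 30\]; the risk parameter 20
#' log-spaced points on \[0.2, 5\]. `scale` shrinks every grid by the same
#' factor (e.g. `scale = 0.6` gives 30/24/12 points) for faster, coarser
#' fits; expected parameters are insensitive to refinement beyond the
#' defaults (see the package vignette).
#'
#' @param variant Model variant, `"m1"` ... `"m5"`.
#' @param scale Multiplier on the number of grid points per dimension.
#' @return Named list of strictly increasing numeric grids, one per free
#'   parameter of the variant.
#' @export
default_param_grid <- function(variant = c("m1", "m2", "m3", "m4", "m5"),
                               scale = 1) {
  variant <- match.arg(variant)
  npt <- function(n) max(2L, as.integer(round(n * scale)))
  lr <- seq(0.01, 0.99, length.out = npt(50L))
  beta <- exp(seq(log(0.1), log(30), length.out = npt(40L)))
  gam <- exp(seq(log(0.2), log(5), length.out = npt(20L)))
  switch(variant,
         m1 = list(alpha_win = lr, alpha_loss = lr,
                   beta_win = beta, beta_loss = beta),
         m2 = list(alpha_value = lr, beta_single = beta),
         m3 = list(beta_win = beta, beta_loss = beta),
         m4 = list(alpha_win = lr, alpha_loss = lr, beta_single = beta),
         m5 = list(alpha_win = lr, alpha_loss = lr, beta_single = beta,
                   gamma = gam))
}

included_trials <- function(n, exclude_first) {
  if (exclude_first >= n) {
    stop("excluding the first ", exclude_first,
         " trials leaves no choice data")
  }
  seq_len(n) > exclude_first
}

#' Choice log-likelihood of one block under fixed parameters
#'
#' Runs the model's belief updating from trial 1 but sums the Bernoulli
#' choice log-likelihood only over trials after the first `exclude_first`
#' (early trials are excluded from estimation, matching their exclusion from
#' the pupillometry analysis; learning still passes through them).
#' Choice probabilities are floored at 1e-12 before the log.
#'
#' @param variant Model variant.
#' @param schedule Outcome schedule (or trial data frame) for the block.
#' @param choices Character vector of choices, `"A"`/`"B"`, one per trial.
#' @param params Named list of model parameters.
#' @param exclude_first Number of initial trials excluded from the sum
#'   (default 10).
#' @return The summed log-likelihood (scalar).
#' @export
block_loglik <- function(variant, schedule, choices, params,
                         exclude_first = 10L) {
  n <- nrow(as.data.frame(schedule))
  if (length(choices) != n) stop("choices do not align with the schedule")
  traj <- model_variant_run(variant, schedule, params)
  inc <- included_trials(n, exclude_first)
  p <- ifelse(choices == "A", traj$p_choose_A, 1 - traj$p_choose_A)
  sum(log(pmax(p[inc], 1e-12)))
}

# Belief-trajectory matrices and kernel dispatch: log-likelihood over the
# full grid, returned as an array with one dimension per free parameter.
grid_loglik_array <- function(variant, schedule, choices, grid,
                              exclude_first = 10L) {
  ind <- outcome_indicators(schedule)
  n <- length(ind$win)
  if (length(choices) != n) stop("choices do not align with the schedule")
  inc <- included_trials(n, exclude_first)
  choiceA <- as.integer(choices == "A")

  if (variant == "m1" || variant == "m4") {
    Rw <- rw_filter_grid(ind$win, grid$alpha_win)
    Rl <- rw_filter_grid(ind$loss, grid$alpha_loss)
    if (variant == "m1") {
      return(grid_loglik_cpp(Rw, Rl, grid$beta_win, grid$beta_loss,
                             choiceA, inc, FALSE))
    }
    return(grid_loglik_cpp(Rw, Rl, grid$beta_single, numeric(0),
                           choiceA, inc, TRUE))
  }
  if (variant == "m5") {
    Rw <- rw_filter_grid(ind$win, grid$alpha_win)
    Rl <- rw_filter_grid(ind$loss, grid$alpha_loss)
    slices <- lapply(grid$gamma, function(g) {
      if (g == 1) {
        Rwg <- Rw
        Rlg <- Rl
      } else {
        Rwg <- risk_transform(pmax(Rw, 1e-12), g)
        Rlg <- risk_transform(pmax(Rl, 1e-12), g)
      }
      grid_loglik_cpp(Rwg, Rlg, grid$beta_single, numeric(0), choiceA, inc,
                      TRUE)
    })
    ll <- array(unlist(slices),
                c(length(grid$alpha_win), length(grid$alpha_loss),
                  length(grid$beta_single), length(grid$gamma)))
    return(ll)
  }
  if (variant == "m2") {
    out <- ind$win - ind$loss
    K <- length(grid$alpha_value)
    V <- matrix(NA_real_, n, K)
    v <- numeric(K)
    for (i in seq_len(n)) {
      V[i, ] <- v
      v <- v + grid$alpha_value * (out[i] - v)
    }
    ll <- sapply(grid$beta_single, function(b) {
      P <- plogis(2 * b * V)
      P <- ifelse(matrix(choiceA == 1L, n, K), P, 1 - P)
      colSums(log(pmax(P[inc, , drop = FALSE], 1e-12)))
    })
    return(array(ll, c(K, length(grid$beta_single))))
  }
  if (variant == "m3") {
    rw <- bayesian_learner(ind$win)$r_hat
    rl <- bayesian_learner(ind$loss)$r_hat
    ll <- grid_loglik_cpp(matrix(rw, ncol = 1), matrix(rl, ncol = 1),
                          grid$beta_win, grid$beta_loss, choiceA, inc, FALSE)
    return(array(ll, c(length(grid$beta_win), length(grid$beta_loss))))
  }
  stop("unknown model variant: ", variant)
}

check_grid <- function(grid, variant) {
  expected <- model_param_names(variant)
  if (!identical(sort(names(grid)), sort(expected))) {
    stop("grid dimensions (", paste(names(grid), collapse = ", "),
         ") do not match the free parameters of ", variant)
  }
  for (nm in expected) {
    g <- grid[[nm]]
    if (length(g) < 2L || any(diff(g) <= 0)) {
      stop("grid for ", nm, " must be strictly increasing with >= 2 points")
    }
  }
  grid[expected]
}

#' Full joint grid posterior over model parameters for one block
#'
#' Evaluates the block's choice log-likelihood at every point of the
#' parameter grid, multiplies by the prior (uniform by default) and
#' normalises, working in log space for stability.
#'
#' @inheritParams block_loglik
#' @param grid Named list of parameter grids, as from [default_param_grid()].
#' @param prior Optional array of prior weights with one dimension per grid
#'   (need not be normalised); `NULL` means uniform.
#' @return An object of class `grid_posterior`: list with `posterior` (array
#'   summing to 1), `grid`, `variant` and `loglik` (the log-likelihood
#'   array).
#' @export
grid_posterior <- function(variant, schedule, choices, grid = NULL,
                           exclude_first = 10L, prior = NULL) {
  if (is.null(grid)) grid <- default_param_grid(variant)
  grid <- check_grid(grid, variant)
  ll <- grid_loglik_array(variant, schedule, choices, grid, exclude_first)
  lp <- ll - max(ll)
  w <- exp(lp)
  if (!is.null(prior)) {
    stopifnot(identical(dim(prior), dim(w)))
    if (any(prior < 0)) stop("prior weights must be non-negative")
    w <- w * prior
  }
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) {
    stop("posterior mass underflowed to zero; check the data and grid")
  }
  structure(list(posterior = w / tot, grid = grid, variant = variant,
                 loglik = ll),
            class = "grid_posterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Marginal posterior expectation of one parameter
#'
#' Sums the joint grid posterior over all other parameter dimensions and
#' returns the expectation of the marginal.
#'
#' @param posterior A `grid_posterior`.
#' @param parameter Parameter name (or dimension index).
#' @return Scalar expected value.
#' @export
marginal_expectation <- function(posterior, parameter) {
  stopifnot(inherits(posterior, "grid_posterior"))
  d <- if (is.character(parameter)) {
    match(parameter, names(posterior$grid))
  } else as.integer(parameter)
  if (is.na(d) || d < 1L || d > length(posterior$grid)) {
    stop("unknown parameter: ", parameter)
  }
  marg <- apply(posterior$posterior, d, sum)
  sum(marg * posterior$grid[[d]])
}

#' Fit one participant's choices with a model variant
#'
#' Fits each of the participant's blocks independently: full grid posterior,
#' marginal expected value of every parameter, log-likelihood re-evaluated
#' at the expected parameters, and block BIC
#' `k * log(n) - 2 * loglik` with `k` the variant's free-parameter count and
#' `n` the number of likelihood-contributing trials. `bic_total` sums the
#' blocks.
#'
#' @param variant Model variant.
#' @param trials Data frame of one participant's trials with columns
#'   `block`, `trial`, `choice`, `win_side`, `loss_side`.
#' @param grid Parameter grids (default [default_param_grid()]).
#' @param exclude_first Initial trials excluded per block (default 10).
#' @return An object of class `model_fit`: list with `variant`, `params`
#'   (data frame, one row per block of expected parameters), `loglik`, `n`,
#'   `bic` (per-block vectors) and `bic_total`.
#' @export
fit_participant <- function(variant, trials, grid = NULL,
                            exclude_first = 10L) {
  if (is.null(grid)) grid <- default_param_grid(variant)
  grid <- check_grid(grid, variant)
  blocks <- sort(unique(trials$block))
  k <- length(grid)
  params <- list(); loglik <- numeric(0); nn <- integer(0)
  for (b in blocks) {
    tb <- trials[trials$block == b, , drop = FALSE]
    gp <- grid_posterior(variant, tb, tb$choice, grid, exclude_first)
    est <- lapply(names(grid), function(p) marginal_expectation(gp, p))
    names(est) <- names(grid)
    ll <- block_loglik(variant, tb, tb$choice, est, exclude_first)
    params[[as.character(b)]] <- as.data.frame(est)
    loglik <- c(loglik, ll)
    nn <- c(nn, nrow(tb) - exclude_first)
  }
  pdf <- do.call(rbind, params)
  pdf <- cbind(block = blocks, pdf)
  rownames(pdf) <- NULL
  bic <- k * log(nn) - 2 * loglik
  structure(list(variant = variant, params = pdf, loglik = loglik,
                 n = nn, bic = bic, bic_total = sum(bic), k = k,
                 participant = attr(trials, "participant", exact = TRUE)),
            class = "model_fit")
}

#' Map fitted parameters onto the real line
#'
#' Learning rates (parameters named `alpha*`) are logit-transformed from
#' (0, 1) onto the real line; inverse temperatures (`beta*`) are
#' log-transformed. Other parameters are returned unchanged. Values at the
#' boundary are clamped to 1e-6 (or 1 - 1e-6) with a warning.
#'
#' @param fit A `model_fit`, or a data frame of parameter columns.
#' @return Data frame of the same shape with transformed values.
#' @export
transform_params <- function(fit) {
  pdf <- if (inherits(fit, "model_fit")) fit$params else as.data.frame(fit)
  out <- pdf
  for (nm in names(out)) {
    x <- out[[nm]]
    if (grepl("^alpha", nm)) {
      if (any(x <= 0 | x >= 1)) {
        warning("learning rate at boundary clamped to [1e-6, 1 - 1e-6]")
        x <- pmin(pmax(x, 1e-6), 1 - 1e-6)
      }
      out[[nm]] <- qlogis(x)
    } else if (grepl("^beta", nm)) {
      if (any(x <= 0)) {
        warning("inverse temperature at boundary clamped to 1e-6")
        x <- pmax(x, 1e-6)
      }
      out[[nm]] <- log(x)
    }
  }
  out
}

#' Compare model variants across a cohort by BIC
#'
#' @param fit_table Data frame with columns `participant`, `variant`,
#'   `bic_total` (one row per participant x variant), or a list of
#'   `model_fit` objects carrying `participant` ids.
#' @return List with `summary` (per variant: mean BIC, SEM, n) and `best`
#'   (per participant: the lowest-BIC variant, `NA` on an exact tie).
#' @export
compare_models <- function(fit_table) {
  if (is.list(fit_table) && !is.data.frame(fit_table)) {
    fit_table <- do.call(rbind, lapply(fit_table, function(f) {
      data.frame(participant = f$participant %||% NA,
                 variant = f$variant, bic_total = f$bic_total,
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("participant", "variant", "bic_total") %in%
                  names(fit_table)))
  agg <- aggregate(bic_total ~ variant, fit_table, function(x) {
    c(mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x))
  })
  summary <- data.frame(variant = agg$variant,
                        mean_bic = agg$bic_total[, "mean"],
                        sem_bic = agg$bic_total[, "sem"],
                        n = agg$bic_total[, "n"],
                        stringsAsFactors = FALSE)
  best <- do.call(rbind, lapply(split(fit_table, fit_table$participant),
                                function(d) {
    mn <- min(d$bic_total)
    winners <- d$variant[d$bic_total == mn]
    data.frame(participant = d$participant[1],
               best_variant = if (length(winners) == 1L) winners else NA,
               tie = length(winners) > 1L, stringsAsFactors = FALSE)
  }))
  rownames(best) <- NULL
  list(summary = summary, best = best)
}
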