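#' Rescorla-Wagner update of an outcome-probability estimate
#'
#' Moves the current estimate `r` a fraction `alpha` of the way towards the
#' observed outcome indicator.
#'
#' @param r Current estimate in \[0, 1\].
#' @param alpha Learning rate in \[0, 1\].
#' @param outcome_on_A 0/1 indicator that the outcome fell on shape A.
#' @return Updated estimate, guaranteed to stay in \[0, 1\].
#' @export
rw_update <- function(r, alpha, outcome_on_A) {
  if (any(alpha < 0 | alpha > 1)) stop("`alpha` must lie in [0, 1]")
  stopifnot(all(r >= 0 & r <= 1), all(outcome_on_A %in% c(0, 1)))
  r + alpha * (outcome_on_A - r)
}

#' Softmax choice probability with valence-specific inverse temperatures
#'
#' Combines the two outcome-probability estimates into a probability of
#' choosing shape A: the logistic of
#' `beta_win * r_win - beta_loss * r_loss`.
#'
#' @param r_win,r_loss Estimated probabilities that the win/loss is under A.
#' @param beta_win,beta_loss Inverse decision temperatures (>= 0).
#' @return Probability of choosing A, strictly inside (0, 1).
#' @export
choice_prob_two_beta <- function(r_win, r_loss, beta_win, beta_loss) {
  stopifnot(all(is.finite(r_win)), all(is.finite(r_loss)),
            all(is.finite(beta_win)), all(is.finite(beta_loss)))
  plogis(beta_win * r_win - beta_loss * r_loss)
}

#' Non-linear risk distortion of a probability estimate
#'
#' Applies `2^(-(-log2(r))^gamma)`. `gamma = 1` is the identity; other
#' values warp probabilities most strongly near 0 and 1, capturing
#' non-normative weighting of extreme probabilities.
#'
#' @param r Probability in (0, 1\].
#' @param gamma Risk parameter (> 0).
#' @return Distorted probability in (0, 1\].
#' @export
risk_transform <- function(r, gamma) {
  if (any(gamma <= 0)) stop("`gamma` must be positive")
  if (any(r <= 0)) stop("`r` must be positive (log of zero is undefined)")
  stopifnot(all(r <= 1))
  if (identical(gamma, 1) || identical(gamma, 1L)) return(r)  # exact identity
  2^(-((-log2(r))^gamma))
}

# Sequential RW filter: beliefs held *entering* each trial, initialised at
# `init`, updated with the outcome of each trial after it is used.
# Vectorised over a grid of learning rates; returns a T x K matrix.
rw_filter_grid <- function(out01, alphas, init = 0.5) {
  n <- length(out01)
  K <- length(alphas)
  R <- matrix(NA_real_, n, K)
  r <- rep(init, K)
  for (i in seq_len(n)) {
    R[i, ] <- r
    r <- r + alphas * (out01[i] - r)
  }
  R
}

# Keep choice probabilities strictly inside (0, 1): the package-wide 1e-12
# floor applied before any likelihood logarithm.
clamp_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

outcome_indicators <- function(schedule) {
  list(win = as.numeric(schedule$win_side == "A"),
       loss = as.numeric(schedule$loss_side == "A"))
}

check_params <- function(params, needed, variant) {
  missing <- setdiff(needed, names(params))
  extra <- setdiff(names(params),
                   c(needed, "participant"))
  if (length(missing)) {
    stop("model ", variant, " requires parameter(s): ",
         paste(missing, collapse = ", "))
  }
  if (length(extra)) {
    stop("parameter(s) not used by model ", variant, ": ",
         paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

#' Free parameters of a model variant
#'
#' @param variant Model variant, `"m1"` ... `"m5"`.
#' @return Character vector of the variant's free-parameter names.
#' @export
model_param_names <- function(variant) {
  switch(variant,
         m1 = c("alpha_win", "alpha_loss", "beta_win", "beta_loss"),
         m2 = c("alpha_value", "beta_single"),
         m3 = c("beta_win", "beta_loss"),
         m4 = c("alpha_win", "alpha_loss", "beta_single"),
         m5 = c("alpha_win", "alpha_loss", "beta_single", "gamma"),
         stop("unknown model variant: ", variant))
}

#' Run a behavioural model over one block's outcome schedule
#'
#' Computes the per-trial belief trajectory and choice probabilities for one
#' of the five model variants. Beliefs available on trial `i` reflect
#' outcomes up to trial `i - 1` only. Because both outcome locations are
#' revealed on every trial regardless of choice, the trajectories do not
#' depend on the choices actually made, so the same run serves both
#' generative simulation and likelihood evaluation.
#'
#' Variants: `m1` -- independent RW estimates of the win and loss location
#' with valence-specific learning rates and inverse temperatures (the
#' primary model); `m2` -- model-free learner of a single net shape value
#' (initialised at 0) with one learning rate and one temperature; `m3` --
#' the Bayesian volatility-tracking learner (no learning-rate parameters)
#' with two temperatures; `m4` -- `m1` with a single shared temperature;
#' `m5` -- `m4` with a risk distortion [risk_transform()] applied to both
#' probability estimates before the softmax.
#'
#' @param variant One of `"m1"` ... `"m5"`.
#' @param schedule An `outcome_schedule` (or data frame with `win_side`,
#'   `loss_side`).
#' @param params Named list of the variant's parameters; see
#'   [model_param_names()]. Exactly the variant's parameters must be given.
#' @return A data frame with one row per trial: `trial`, `r_win`, `r_loss`
#'   (for `m2`, `v_A` instead), and `p_choose_A`.
#' @export
model_variant_run <- function(variant = c("m1", "m2", "m3", "m4", "m5"),
                              schedule, params = list()) {
  variant <- match.arg(variant)
  check_params(params, model_param_names(variant), variant)
  ind <- outcome_indicators(schedule)
  n <- length(ind$win)

  if (variant == "m2") {
    out <- ind$win - ind$loss
    v <- numeric(n)
    cur <- 0
    for (i in seq_len(n)) {
      v[i] <- cur
      cur <- cur + params$alpha_value * (out[i] - cur)
    }
    # Both shapes observed every trial, so v_B = -v_A exactly and the
    # softmax acts on v_A - v_B = 2 v_A.
    p <- clamp_prob(plogis(params$beta_single * (2 * v)))
    return(data.frame(trial = seq_len(n), v_A = v, p_choose_A = p))
  }

  if (variant == "m3") {
    rw <- bayesian_learner(ind$win)$r_hat
    rl <- bayesian_learner(ind$loss)$r_hat
    p <- clamp_prob(choice_prob_two_beta(rw, rl, params$beta_win,
                                         params$beta_loss))
    return(data.frame(trial = seq_len(n), r_win = rw, r_loss = rl,
                      p_choose_A = p))
  }

  rw <- drop(rw_filter_grid(ind$win, params$alpha_win))
  rl <- drop(rw_filter_grid(ind$loss, params$alpha_loss))
  if (variant == "m5" && params$gamma != 1) {
    rw_c <- risk_transform(pmax(rw, 1e-12), params$gamma)
    rl_c <- risk_transform(pmax(rl, 1e-12), params$gamma)
  } else {
    rw_c <- rw
    rl_c <- rl
  }
  bw <- if (variant == "m1") params$beta_win else params$beta_single
  bl <- if (variant == "m1") params$beta_loss else params$beta_single
  p <- clamp_prob(choice_prob_two_beta(rw_c, rl_c, bw, bl))
  data.frame(trial = seq_len(n), r_win = rw, r_loss = rl, p_choose_A = p)
}

#' @rdname model_variant_run
#' @export
model1_run <- function(schedule, params) {
  model_variant_run("m1", schedule, params)
}

#' @rdname model_variant_run
#' @export
model2_run <- function(schedule, params) {
  model_variant_run("m2", schedule, params)
}

#' @rdname model_variant_run
#' @param beta_win,beta_loss Inverse temperatures for the choice stage of the
#'   Bayesian-learner variant.
#' @export
model3_run <- function(schedule, beta_win = 1, beta_loss = 1) {
  model_variant_run("m3", schedule,
                    list(beta_win = beta_win, beta_loss = beta_loss))
}
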