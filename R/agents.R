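#' Simulate one agent's choices on a session schedule
#'
#' Samples choices trial-by-trial from the model's choice probabilities and
#' computes the monetary consequence of each choice: +15 pence when the
#' chosen shape carries the win only, -15 when it carries the loss only, and
#' 0 when it carries both or neither.
#'
#' @param variant Model variant used generatively.
#' @param params Named list of the variant's parameters, or a list of such
#'   lists (one per block) for agents whose parameters adapt across blocks.
#' @param session A `session_schedule` from [generate_session()].
#' @param seed Integer seed for the choice draws.
#' @param participant_id Optional identifier stored with the data.
#' @return A data frame of class `session_data` with columns `block`,
#'   `trial`, `choice`, `win_side`, `loss_side`, `earnings_delta`;
#'   attributes `participant` and `block_order`.
#' @export
simulate_agent <- function(variant, params, session, seed = NULL,
                           participant_id = NA) {
  stopifnot(inherits(session, "session_schedule"))
  per_block <- is.null(names(params))
  if (per_block && length(params) != length(session$blocks)) {
    stop("per-block `params` must supply one parameter set per block")
  }
  with_local_seed(seed, {
    rows <- lapply(seq_along(session$blocks), function(b) {
      sched <- session$blocks[[b]]
      traj <- model_variant_run(variant, sched,
                                if (per_block) params[[b]] else params)
      choice <- ifelse(rbinom(nrow(sched), 1L, traj$p_choose_A) == 1L,
                       "A", "B")
      won <- sched$win_side == choice
      lost <- sched$loss_side == choice
      data.frame(block = b, trial = sched$trial, choice = choice,
                 win_side = sched$win_side, loss_side = sched$loss_side,
                 earnings_delta = 15L * won - 15L * lost,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "participant") <- participant_id
    attr(out, "block_order") <- session$block_order
    class(out) <- c("session_data", "data.frame")
    out
  })
}

#' Default cohort parameter sampler for the primary model
#'
#' Learning rates are drawn uniformly from (0.05, 0.6) and inverse
#' temperatures uniformly from (2, 10), independently per valence --
#' a realistic spread for this task family, wide enough to probe parameter
#' recovery across the useful range.
#'
#' @return A named list of `m1` parameters.
#' @export
sample_m1_params <- function() {
  list(alpha_win = runif(1, 0.05, 0.6),
       alpha_loss = runif(1, 0.05, 0.6),
       beta_win = runif(1, 2, 10),
       beta_loss = runif(1, 2, 10))
}

#' Simulate a cohort of behavioural agents
#'
#' Generates `n` participants, each with their own task-schedule realisation
#' and model parameters drawn from `param_sampler`. The first half of the
#' cohort (rounding down) completes the win-volatile block second; the rest
#' complete the loss-volatile block second, mirroring study
#' counterbalancing.
#'
#' @param n Cohort size (>= 2).
#' @param variant Generative model variant.
#' @param param_sampler Function returning a named parameter list per
#'   participant; default [sample_m1_params()] (only valid for `m1`).
#' @param seed Master seed; fanned out per participant.
#' @return List with `sessions` (list of `session_data`), `schedules`
#'   (list of `session_schedule`), and `ground_truth` (data frame of the
#'   generating parameters, one row per participant).
#' @export
simulate_cohort <- function(n, variant = "m1",
                            param_sampler = sample_m1_params, seed = NULL) {
  stopifnot(n >= 2L)
  seeds <- derive_seeds(seed, 3L * n)
  orders <- rep(c("win_volatile_first", "loss_volatile_first"),
                c(n %/% 2L, n - n %/% 2L))
  sessions <- vector("list", n)
  schedules <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- generate_session(orders[i], seed = seeds[3L * i - 2L])
    params <- with_local_seed(seeds[3L * i - 1L], param_sampler())
    sessions[[i]] <- simulate_agent(variant, params, sched,
                                    seed = seeds[3L * i],
                                    participant_id = i)
    schedules[[i]] <- sched
    truth[[i]] <- cbind(data.frame(participant = i, block_order = orders[i],
                                   stringsAsFactors = FALSE),
                        as.data.frame(params))
  }
  list(sessions = sessions, schedules = schedules,
       ground_truth = do.call(rbind, truth))
}
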