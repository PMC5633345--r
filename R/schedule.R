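#' Block specification for the dual-valence learning task
#'
#' Describes one 80-trial task block. Win and loss outcomes are positioned
#' independently of each other; each valence is either *volatile* (its
#' probability of appearing under shape A alternates between the two
#' `volatile_levels` in runs of `run_length_range` trials) or *stable*
#' (fixed at `stable_level`).
#'
#' @param block_type One of `"both_volatile"`, `"win_volatile_loss_stable"`,
#'   `"loss_volatile_win_stable"`.
#' @param n_trials Number of trials in the block (default 80).
#' @param volatile_levels Length-2 numeric, the two probability levels a
#'   volatile trajectory alternates between (default `c(0.15, 0.85)`).
#' @param stable_level Probability used for a stable trajectory (default 0.5).
#' @param run_length_range Inclusive integer bounds on volatile run lengths
#'   (default `c(14, 30)`).
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(block_type = c("both_volatile",
                                      "win_volatile_loss_stable",
                                      "loss_volatile_win_stable"),
                       n_trials = 80L,
                       volatile_levels = c(0.15, 0.85),
                       stable_level = 0.5,
                       run_length_range = c(14L, 30L)) {
  block_type <- match.arg(block_type)
  n_trials <- as.integer(n_trials)
  stopifnot(length(n_trials) == 1L, n_trials >= 1L,
            length(volatile_levels) == 2L,
            all(volatile_levels > 0 & volatile_levels < 1),
            length(stable_level) == 1L,
            stable_level > 0 && stable_level < 1,
            length(run_length_range) == 2L)
  run_length_range <- as.integer(run_length_range)
  if (any(run_length_range < 1L) ||
      run_length_range[1] > run_length_range[2]) {
    stop("`run_length_range` must be ordered and positive")
  }
  structure(list(block_type = block_type,
                 n_trials = n_trials,
                 volatile_levels = sort(volatile_levels),
                 stable_level = stable_level,
                 run_length_range = run_length_range),
            class = "block_spec")
}

# Roles ("volatile"/"stable") of the win and loss trajectories for a block type.
block_roles <- function(block_type) {
  switch(block_type,
         both_volatile = c(win = "volatile", loss = "volatile"),
         win_volatile_loss_stable = c(win = "volatile", loss = "stable"),
         loss_volatile_win_stable = c(win = "stable", loss = "volatile"),
         stop("unknown block type: ", block_type))
}

# Sample alternating run lengths that fill `n_trials` exactly, with every run
# length inside [lo, hi] and trials split equally between the two levels.
# Run lengths are drawn uniformly; the boundary between the final two runs is
# then shifted to make the split exact, resampling whenever the shift would
# push a run outside [lo, hi].
sample_balanced_runs <- function(n_trials, lo, hi) {
  if (n_trials < 2L * lo) {
    stop("n_trials (", n_trials, ") cannot fit two runs of minimum length ",
         lo)
  }
  if (n_trials %% 2L != 0L) {
    stop("exact 50% balancing requires an even number of trials")
  }
  half <- n_trials %/% 2L
  repeat {
    lens <- integer(0)
    tot <- 0L
    while (tot < n_trials) {
      l <- sample(lo:hi, 1L)
      lens <- c(lens, l)
      tot <- tot + l
    }
    k <- length(lens)
    lens[k] <- n_trials - sum(lens[-k])
    if (lens[k] < lo || k < 2L) next
    # Surplus of the starting level: runs 1, 3, 5, ... carry level 1.
    d <- sum(lens[seq(1L, k, by = 2L)]) - half
    # Moving the boundary between the last two runs by t trials changes the
    # count of run (k-1)'s level by -t and of run k's level by +t.
    t_shift <- if ((k - 1L) %% 2L == 1L) d else -d
    lens[k - 1L] <- lens[k - 1L] - t_shift
    lens[k] <- lens[k] + t_shift
    if (all(lens >= lo & lens <= hi)) return(lens)
  }
}

# One volatile probability trajectory: alternating levels, balanced runs,
# starting level chosen by fair coin.
volatile_trajectory <- function(spec) {
  lo <- spec$run_length_range[1]
  hi <- spec$run_length_range[2]
  lens <- sample_balanced_runs(spec$n_trials, lo, hi)
  start_high <- sample(c(TRUE, FALSE), 1L)
  levels <- if (start_high) rev(spec$volatile_levels) else spec$volatile_levels
  rep(rep_len(levels, length(lens)), lens)
}

#' Generate one task-block outcome schedule
#'
#' Builds the per-trial win and loss probability trajectories for a block and
#' realises the outcome sides. Volatile trajectories alternate between the
#' two volatile levels in runs of 14--30 trials, constructed so the mean
#' probability over the block is exactly 50%; stable trajectories are
#' constant at 50%. Win and loss sides are drawn independently per trial.
#'
#' @param spec A [block_spec()].
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An `outcome_schedule`: a data frame with one row per trial and
#'   columns `trial`, `p_win_A`, `p_loss_A`, `win_side`, `loss_side`
#'   (sides coded `"A"`/`"B"`), with the block type stored as an attribute.
#' @export
generate_block <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "block_spec"))
  with_local_seed(seed, {
    roles <- block_roles(spec$block_type)
    traj <- lapply(roles, function(role) {
      if (role == "volatile") volatile_trajectory(spec)
      else rep(spec$stable_level, spec$n_trials)
    })
    win_side <- ifelse(rbinom(spec$n_trials, 1L, traj$win) == 1L, "A", "B")
    loss_side <- ifelse(rbinom(spec$n_trials, 1L, traj$loss) == 1L, "A", "B")
    out <- data.frame(trial = seq_len(spec$n_trials),
                      p_win_A = traj$win,
                      p_loss_A = traj$loss,
                      win_side = win_side,
                      loss_side = loss_side,
                      stringsAsFactors = FALSE)
    attr(out, "block_type") <- spec$block_type
    class(out) <- c("outcome_schedule", "data.frame")
    out
  })
}

#' Generate a full three-block session schedule
#'
#' Block 1 has both outcomes volatile; blocks 2 and 3 are the two
#' single-volatile blocks, in the order given by `order` (counterbalanced
#' across participants in a study).
#'
#' @param order `"win_volatile_first"` or `"loss_volatile_first"`: which
#'   single-volatile block comes second.
#' @param seed Integer seed.
#' @param n_trials Trials per block (default 80).
#' @return A `session_schedule`: list with `blocks` (three
#'   `outcome_schedule`s) and `block_order`.
#' @export
generate_session <- function(order = c("win_volatile_first",
                                       "loss_volatile_first"),
                             seed = NULL, n_trials = 80L) {
  order <- match.arg(order)
  seeds <- derive_seeds(seed, 3L)
  types <- c("both_volatile",
             if (order == "win_volatile_first") {
               c("win_volatile_loss_stable", "loss_volatile_win_stable")
             } else {
               c("loss_volatile_win_stable", "win_volatile_loss_stable")
             })
  blocks <- lapply(seq_along(types), function(b) {
    generate_block(block_spec(types[b], n_trials = n_trials), seeds[b])
  })
  structure(list(blocks = blocks, block_order = order),
            class = "session_schedule")
}

#' @export
as.data.frame.session_schedule <- function(x, ...) {
  rows <- lapply(seq_along(x$blocks), function(b) {
    df <- as.data.frame(unclass(x$blocks[[b]]), stringsAsFactors = FALSE)
    cbind(block = b, df)
  })
  do.call(rbind, rows)
}

# Run-length encoding of a probability trajectory.
trajectory_runs <- function(p) rle(p)$lengths

#' Validate an outcome schedule against its block specification
#'
#' Checks, separately for the win and loss trajectories: that only the
#' permitted probability levels occur; that (for a volatile role) every run
#' length is inside the specified range; and that the block-mean probability
#' is 50% (exact for volatile roles up to numeric tolerance, constant for
#' stable roles).
#'
#' @param sched An `outcome_schedule` (or data frame with the same columns).
#' @param spec The [block_spec()] it should satisfy.
#' @return A data frame with columns `valence`, `check`, `pass`; attribute
#'   `"pass"` gives the conjunction.
#' @export
validate_schedule <- function(sched, spec) {
  stopifnot(inherits(spec, "block_spec"))
  roles <- block_roles(spec$block_type)
  lo <- spec$run_length_range[1]
  hi <- spec$run_length_range[2]
  res <- list()
  for (val in c("win", "loss")) {
    p <- sched[[paste0("p_", val, "_A")]]
    role <- roles[[val]]
    if (role == "volatile") {
      levels_ok <- all(p %in% spec$volatile_levels)
      runs <- trajectory_runs(p)
      runs_ok <- length(runs) >= 2L && all(runs >= lo & runs <= hi)
      mean_ok <- abs(mean(p) - 0.5) <= 1e-9
    } else {
      levels_ok <- all(p == spec$stable_level)
      runs_ok <- TRUE
      mean_ok <- abs(mean(p) - 0.5) <= 1e-9
    }
    res[[val]] <- data.frame(
      valence = val,
      check = c("levels", "run_lengths", "mean_50"),
      pass = c(levels_ok, runs_ok, mean_ok),
      stringsAsFactors = FALSE)
  }
  len_ok <- length(sched$p_win_A) == spec$n_trials &&
    length(sched$p_loss_A) == spec$n_trials &&
    length(sched$win_side) == spec$n_trials &&
    length(sched$loss_side) == spec$n_trials
  out <- rbind(data.frame(valence = "both", check = "lengths", pass = len_ok,
                          stringsAsFactors = FALSE),
               res$win, res$loss)
  attr(out, "pass") <- all(out$pass)
  out
}
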