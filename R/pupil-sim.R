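#' Generator settings for synthetic pupil traces
#'
#' Defaults emulate an eye-tracker recording pupil area at 500 Hz during the
#' task: a slow multi-sinusoid drift, white measurement noise, blink
#' dropouts, and an outcome-locked dilation shaped as a gamma impulse
#' peaking ~1.5 s after outcome onset with 6 s support. Amplitudes are in
#' arbitrary pupil-area units around `baseline_level`.
#'
#' @param fs Sampling rate in Hz.
#' @param trial_dur_s Seconds between consecutive outcome presentations.
#' @param outcome_latency_s Outcome onset within a trial, in seconds (must
#'   leave a full 1 s pre-outcome baseline window).
#' @param baseline_level Mean pupil area.
#' @param base_amp_win,base_amp_loss Dilation amplitude evoked by outcome
#'   presentation regardless of where the outcome fell; losses dilate more
#'   than wins.
#' @param kernel_shape,kernel_scale Gamma-kernel shape/scale (seconds).
#' @param kernel_support_s Kernel support, matching the 6 s analysis window.
#' @param blink_rate_hz Mean blink rate (blinks per second).
#' @param blink_dur_range_s Uniform range of blink durations (seconds).
#' @param noise_sd White-noise standard deviation.
#' @param drift_amp Amplitude of the slow drift component.
#' @return List of class `pupil_gen_params`.
#' @export
pupil_gen_params <- function(fs = 500, trial_dur_s = 8,
                             outcome_latency_s = 1.5, baseline_level = 5,
                             base_amp_win = 0.4, base_amp_loss = 0.7,
                             kernel_shape = 3, kernel_scale = 0.75,
                             kernel_support_s = 6,
                             blink_rate_hz = 0.1,
                             blink_dur_range_s = c(0.1, 0.4),
                             noise_sd = 0.3, drift_amp = 0.8) {
  stopifnot(fs > 0, trial_dur_s > outcome_latency_s,
            outcome_latency_s >= 1, all(blink_dur_range_s > 0),
            noise_sd >= 0, drift_amp >= 0)
  structure(as.list(environment()), class = "pupil_gen_params")
}

#' Injected obtained-vs-unobtained pupil effect sizes
#'
#' The extra dilation an outcome evokes when it falls on the *chosen* shape
#' relative to the unchosen shape, per valence and per the volatility of
#' that valence in the block. The defaults make the volatility gain larger
#' for losses (0.30) than wins (0.10), the asymmetry the pipeline is
#' designed to detect.
#'
#' @param win_stable,win_volatile,loss_stable,loss_volatile Obtained-minus-
#'   unobtained dilation amplitudes (same units as the trace).
#' @return Named list of class `pupil_effect_spec`.
#' @export
pupil_effect_spec <- function(win_stable = 0.15, win_volatile = 0.25,
                              loss_stable = 0.20, loss_volatile = 0.50) {
  structure(list(win_stable = win_stable, win_volatile = win_volatile,
                 loss_stable = loss_stable, loss_volatile = loss_volatile),
            class = "pupil_effect_spec")
}

# Block types implied by a session's counterbalancing order.
session_block_types <- function(block_order) {
  c("both_volatile",
    if (identical(block_order, "loss_volatile_first")) {
      c("loss_volatile_win_stable", "win_volatile_loss_stable")
    } else {
      c("win_volatile_loss_stable", "loss_volatile_win_stable")
    })
}

#' Simulate a raw pupil trace for one session
#'
#' Builds a continuous 500 Hz trace as baseline + slow drift + white noise +
#' one outcome-locked dilation per trial, with blinks inserted as invalid
#' (NA) dropout intervals. Each trial contributes a win- and a loss-evoked
#' response at a single shared outcome onset; the obtained-vs-unobtained
#' amplitude difference per valence is set by `effect_spec`, keyed to
#' whether that valence is volatile in the trial's block.
#'
#' @param session A `session_data` data frame (see [simulate_agent()]).
#' @param gen [pupil_gen_params()].
#' @param effect_spec [pupil_effect_spec()].
#' @param seed Integer seed.
#' @param block_types Character vector of block types per block; by default
#'   inferred from the session's `block_order` attribute.
#' @return List with `trace` (data frame `time_s`, `pupil`, `valid`) and
#'   `markers` (data frame `block`, `trial`, `event_sample`,
#'   `win_obtained`, `loss_obtained`).
#' @export
simulate_pupil <- function(session, gen = pupil_gen_params(),
                           effect_spec = pupil_effect_spec(), seed = NULL,
                           block_types = NULL) {
  if (is.null(block_types)) {
    block_types <- session_block_types(attr(session, "block_order",
                                            exact = TRUE))
  }
  fs <- gen$fs
  n_trials <- nrow(session)
  n_samples <- as.integer(ceiling(n_trials * gen$trial_dur_s * fs))
  t_s <- (seq_len(n_samples) - 1L) / fs

  kern_t <- seq(0, gen$kernel_support_s, by = 1 / fs)
  kern <- dgamma(kern_t, shape = gen$kernel_shape, scale = gen$kernel_scale)
  kern <- kern / max(kern)

  with_local_seed(seed, {
    drift <- rep(0, n_samples)
    for (f in runif(3, 0.005, 0.05)) {
      drift <- drift + (gen$drift_amp / 3) *
        sin(2 * pi * f * t_s + runif(1, 0, 2 * pi))
    }
    clean <- gen$baseline_level + drift

    onset <- as.integer(round(((seq_len(n_trials) - 1L) * gen$trial_dur_s +
                                 gen$outcome_latency_s) * fs)) + 1L
    win_obt <- session$win_side == session$choice
    loss_obt <- session$loss_side == session$choice
    roles <- lapply(block_types, block_roles)
    for (i in seq_len(n_trials)) {
      role <- roles[[session$block[i]]]
      amp_w <- gen$base_amp_win +
        if (win_obt[i]) effect_spec[[paste0("win_", role[["win"]])]] else 0
      amp_l <- gen$base_amp_loss +
        if (loss_obt[i]) effect_spec[[paste0("loss_", role[["loss"]])]] else 0
      idx <- onset[i]:min(onset[i] + length(kern) - 1L, n_samples)
      clean[idx] <- clean[idx] + (amp_w + amp_l) * kern[seq_along(idx)]
    }
    if (min(clean) <= 0) {
      stop("effect amplitudes produce a non-positive pupil area")
    }

    pupil <- clean + rnorm(n_samples, 0, gen$noise_sd)
    valid <- rep(TRUE, n_samples)
    n_blinks <- rpois(1, gen$blink_rate_hz * n_samples / fs)
    if (n_blinks > 0) {
      starts <- sample.int(n_samples, n_blinks)
      durs <- as.integer(round(runif(n_blinks, gen$blink_dur_range_s[1],
                                     gen$blink_dur_range_s[2]) * fs))
      for (b in seq_len(n_blinks)) {
        idx <- starts[b]:min(starts[b] + durs[b] - 1L, n_samples)
        valid[idx] <- FALSE
      }
      pupil[!valid] <- NA_real_
    }

    list(trace = data.frame(time_s = t_s, pupil = pupil, valid = valid),
         markers = data.frame(block = session$block, trial = session$trial,
                              event_sample = onset,
                              win_obtained = win_obt,
                              loss_obtained = loss_obt))
  })
}
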