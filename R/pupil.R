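#' Linearly interpolate blinks and other invalid samples
#'
#' Fills every invalid run by linear interpolation between the neighbouring
#' valid samples; leading/trailing gaps take the nearest valid value. Every
#' filled sample is flagged.
#'
#' @param pupil Numeric trace (may contain NA at invalid samples).
#' @param valid Logical validity mask; defaults to `!is.na(pupil)`.
#' @return List with `pupil` (gap-filled trace) and `interpolated` (logical
#'   flags).
#' @export
interpolate_blinks <- function(pupil, valid = !is.na(pupil)) {
  stopifnot(length(valid) == length(pupil))
  valid <- valid & !is.na(pupil)
  if (sum(valid) < 2L) {
    stop("fewer than two valid samples; cannot interpolate")
  }
  idx <- seq_along(pupil)
  filled <- approx(idx[valid], pupil[valid], xout = idx, method = "linear",
                   rule = 2)$y
  list(pupil = filled, interpolated = !valid)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies a Butterworth low-pass filter forward and backward
#' (zero phase lag). With the default order-3 design and 3.75 Hz cut-off at
#' 500 Hz, a 0.5 Hz component is passed essentially unattenuated and a
#' 10 Hz component is suppressed below 1% amplitude.
#'
#' @param x Numeric trace (no NAs; interpolate first).
#' @param cutoff Cut-off frequency in Hz.
#' @param fs Sampling rate in Hz (must exceed `2 * cutoff`).
#' @param order Filter order.
#' @return Filtered trace of the same length.
#' @export
lowpass_filter <- function(x, cutoff = 3.75, fs = 500, order = 3) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("invalid cut-off frequency")
  if (fs <= 2 * cutoff) stop("sampling rate must exceed twice the cut-off")
  if (anyNA(x)) stop("trace contains NA; interpolate before filtering")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # Odd-reflection padding keeps start/end transients out of the trace
  # (the underlying filter assumes zero initial conditions).
  n <- length(x)
  P <- min(n - 1L, as.integer(ceiling(6 * fs / cutoff)))
  padded <- c(2 * x[1] - x[seq(P + 1L, 2L)], x,
              2 * x[n] - x[seq(n - 1L, n - P)])
  y <- as.numeric(signal::filtfilt(bf, padded))
  y[(P + 1L):(P + n)]
}

#' Z-transform a trace across the session
#'
#' Centres and scales using the session mean and population (n-denominator)
#' standard deviation.
#'
#' @param x Numeric trace.
#' @return Standardised trace (mean 0, population sd 1).
#' @export
z_transform <- function(x) {
  mu <- mean(x)
  sdp <- sqrt(mean((x - mu)^2))
  if (sdp == 0) stop("trace has zero variance; cannot z-transform")
  (x - mu) / sdp
}

#' Clean a raw pupil trace
#'
#' The session-level preprocessing chain: blink interpolation, zero-phase
#' low-pass Butterworth filtering, and session-wide z-transformation.
#'
#' @param trace Data frame with columns `pupil` and `valid` (see
#'   [simulate_pupil()]), or a numeric vector.
#' @param fs Sampling rate in Hz.
#' @inheritParams lowpass_filter
#' @return List of class `clean_trace`: `signal` (z-scored filtered trace),
#'   `interpolated` (per-sample flags), `fs`.
#' @export
clean_trace <- function(trace, fs = 500, cutoff = 3.75, order = 3) {
  if (is.data.frame(trace)) {
    filled <- interpolate_blinks(trace$pupil, trace$valid)
  } else {
    filled <- interpolate_blinks(trace)
  }
  sig <- z_transform(lowpass_filter(filled$pupil, cutoff, fs, order))
  structure(list(signal = sig, interpolated = filled$interpolated, fs = fs),
            class = "clean_trace")
}

#' Extract baseline-corrected outcome-locked epochs
#'
#' For every trial and valence, cuts a `post_s`-second window starting at
#' the outcome onset and subtracts the mean of the `baseline_s`-second
#' window immediately before onset. Win and loss epochs share the trial's
#' onset and differ in their obtained/not-obtained label. The fraction of
#' interpolated samples is computed over the post-outcome window. Epochs
#' whose windows fall outside the trace are flagged excluded with reason
#' `"edge"`.
#'
#' @param clean A `clean_trace`.
#' @param markers Marker data frame (`block`, `trial`, `event_sample`,
#'   `win_obtained`, `loss_obtained`).
#' @param baseline_s,post_s Baseline and post-outcome window lengths (s).
#' @return Object of class `pupil_epochs`: list with `meta` (one row per
#'   trial x valence: `block`, `trial`, `valence`, `obtained`,
#'   `frac_interpolated`, `included`, `reason`) and `samples` (matrix, one
#'   row per epoch).
#' @export
extract_epochs <- function(clean, markers, baseline_s = 1, post_s = 6) {
  stopifnot(inherits(clean, "clean_trace"))
  fs <- clean$fs
  n_base <- as.integer(round(baseline_s * fs))
  n_post <- as.integer(round(post_s * fs))
  n <- length(clean$signal)
  meta <- list(); samples <- list()
  r <- 0L
  for (i in seq_len(nrow(markers))) {
    on <- markers$event_sample[i]
    ok <- (on - n_base) >= 1L && (on + n_post - 1L) <= n
    if (ok) {
      base_mean <- mean(clean$signal[(on - n_base):(on - 1L)])
      post_idx <- on:(on + n_post - 1L)
      epoch <- clean$signal[post_idx] - base_mean
      frac <- mean(clean$interpolated[post_idx])
    } else {
      epoch <- rep(NA_real_, n_post)
      frac <- NA_real_
    }
    for (val in c("win", "loss")) {
      r <- r + 1L
      meta[[r]] <- data.frame(
        block = markers$block[i], trial = markers$trial[i], valence = val,
        obtained = markers[[paste0(val, "_obtained")]][i],
        frac_interpolated = frac,
        included = ok,
        reason = if (ok) NA_character_ else "edge",
        stringsAsFactors = FALSE)
      samples[[r]] <- epoch
    }
  }
  structure(list(meta = do.call(rbind, meta),
                 samples = do.call(rbind, samples),
                 fs = fs, post_s = post_s),
            class = "pupil_epochs")
}

#' Apply trial-level exclusion rules
#'
#' Excludes epochs with more than `interp_threshold` of their post-outcome
#' window interpolated (reason `"interpolation"`; exactly at threshold is
#' retained) and the first `first_trials` trials of each block (reason
#' `"adaptation"`, reflecting initial pupil adaptation to luminance).
#'
#' @param epochs A `pupil_epochs`.
#' @param interp_threshold Strict exclusion threshold on the interpolated
#'   fraction (default 0.5).
#' @param first_trials Number of initial trials per block to drop
#'   (default 10).
#' @return The `pupil_epochs` with updated `included`/`reason`.
#' @export
apply_exclusions <- function(epochs, interp_threshold = 0.5,
                             first_trials = 10L) {
  stopifnot(inherits(epochs, "pupil_epochs"))
  m <- epochs$meta
  interp <- m$included & !is.na(m$frac_interpolated) &
    m$frac_interpolated > interp_threshold
  m$included[interp] <- FALSE
  m$reason[interp] <- "interpolation"
  adapt <- m$included & m$trial <= first_trials
  m$included[adapt] <- FALSE
  m$reason[adapt] <- "adaptation"
  epochs$meta <- m
  epochs
}

#' Decide whether a participant is excluded from pupillometry
#'
#' A participant is dropped when more than `threshold` of their
#' analysis-eligible trials (those past the adaptation window) were excluded
#' by the interpolation rule.
#'
#' @param epochs A `pupil_epochs` after [apply_exclusions()].
#' @param threshold Exclusion fraction above which the participant is
#'   dropped (default 0.99).
#' @return List with `exclude` (logical) and `fraction` (the excluded
#'   fraction).
#' @export
exclude_participant <- function(epochs, threshold = 0.99) {
  m <- epochs$meta[epochs$meta$valence == "win", ]  # one row per trial
  eligible <- is.na(m$reason) | m$reason != "adaptation"
  frac <- mean(!m$included[eligible])
  list(exclude = frac > threshold, fraction = frac)
}

#' Obtained-vs-unobtained difference timeseries, binned
#'
#' For each block and valence, averages the included epochs in which the
#' outcome fell on the chosen shape and subtracts the average of those in
#' which it fell on the unchosen shape, then bins the difference into
#' `n_bins` consecutive equal bins and also returns its overall mean across
#' the window.
#'
#' @param epochs A `pupil_epochs` (after exclusions).
#' @param n_bins Number of bins across the post-outcome window (default 6,
#'   i.e. 1 s bins for a 6 s window).
#' @return List with `bins` (data frame `block`, `valence`, `bin`,
#'   `difference`), `mean6s` (data frame `block`, `valence`, `mean6s`,
#'   `n_obtained`, `n_unobtained`, `missing`) and `timeseries` (list of
#'   full-resolution difference vectors keyed `"block.valence"`). Cells with
#'   no included epochs on either side are flagged `missing`.
#' @export
difference_timeseries <- function(epochs, n_bins = 6L) {
  stopifnot(inherits(epochs, "pupil_epochs"))
  m <- epochs$meta
  n_post <- ncol(epochs$samples)
  bin_id <- rep(seq_len(n_bins), each = n_post / n_bins, length.out = n_post)
  bins <- list(); means <- list(); ts <- list()
  r <- 0L
  for (b in sort(unique(m$block))) {
    for (val in c("win", "loss")) {
      r <- r + 1L
      sel <- m$block == b & m$valence == val & m$included
      obt <- sel & m$obtained
      unobt <- sel & !m$obtained
      missing <- sum(obt) == 0L || sum(unobt) == 0L
      if (missing) {
        d <- rep(NA_real_, n_post)
      } else {
        d <- colMeans(epochs$samples[obt, , drop = FALSE]) -
          colMeans(epochs$samples[unobt, , drop = FALSE])
      }
      bins[[r]] <- data.frame(block = b, valence = val,
                              bin = seq_len(n_bins),
                              difference = as.numeric(
                                tapply(d, bin_id, mean)),
                              stringsAsFactors = FALSE)
      means[[r]] <- data.frame(block = b, valence = val, mean6s = mean(d),
                               n_obtained = sum(obt),
                               n_unobtained = sum(unobt),
                               missing = missing, stringsAsFactors = FALSE)
      ts[[paste(b, val, sep = ".")]] <- d
    }
  }
  list(bins = do.call(rbind, bins), mean6s = do.call(rbind, means),
       timeseries = ts)
}

#' Full pupillometry preprocessing pipeline for one participant
#'
#' Runs blink interpolation, low-pass filtering, z-transformation, epoch
#' extraction with baseline correction, trial- and participant-level
#' exclusions, and the binned obtained-vs-unobtained difference timeseries.
#'
#' @param trace Raw trace data frame (`time_s`, `pupil`, `valid`).
#' @param markers Marker data frame.
#' @param fs Sampling rate (Hz).
#' @inheritParams lowpass_filter
#' @inheritParams extract_epochs
#' @inheritParams apply_exclusions
#' @return List with `clean`, `epochs`, `difference`, and `participant`
#'   (the [exclude_participant()] decision).
#' @export
preprocess_pupil <- function(trace, markers, fs = 500, cutoff = 3.75,
                             order = 3, baseline_s = 1, post_s = 6,
                             interp_threshold = 0.5, first_trials = 10L) {
  cl <- clean_trace(trace, fs = fs, cutoff = cutoff, order = order)
  ep <- extract_epochs(cl, markers, baseline_s = baseline_s,
                       post_s = post_s)
  ep <- apply_exclusions(ep, interp_threshold = interp_threshold,
                         first_trials = first_trials)
  list(clean = cl, epochs = ep, difference = difference_timeseries(ep),
       participant = exclude_participant(ep))
}
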