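make_clean <- function(signal, fs = 500, interpolated = NULL) {
  structure(list(signal = signal,
                 interpolated = interpolated %||% rep(FALSE, length(signal)),
                 fs = fs),
            class = "clean_trace")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("blink interpolation fills gaps linearly and flags them", {
  out <- interpolate_blinks(c(2, NA, 4))
  expect_equal(out$pupil, c(2, 3, 4))
  expect_identical(out$interpolated, c(FALSE, TRUE, FALSE))

  out3 <- interpolate_blinks(c(0, NA, NA, NA, 4))
  expect_equal(out3$pupil, c(0, 1, 2, 3, 4))

  x <- c(1, 2, 3)
  expect_identical(interpolate_blinks(x)$pupil, x)

  # leading/trailing gaps take the nearest valid value
  edge <- interpolate_blinks(c(NA, 5, 7, NA))
  expect_equal(edge$pupil, c(5, 5, 7, 7))

  expect_error(interpolate_blinks(c(NA, NA, 1)), "fewer than two")
})

test_that("the low-pass filter meets its frequency-response bounds", {
  fs <- 500
  t_s <- seq(0, 20, by = 1 / fs)
  slow <- sin(2 * pi * 0.5 * t_s)
  fast <- sin(2 * pi * 10 * t_s)
  expect_gte(fitted_amplitude(lowpass_filter(slow, fs = fs), 0.5, fs), 0.95)
  expect_lte(fitted_amplitude(lowpass_filter(fast, fs = fs), 10, fs), 0.10)
  # DC gain is 1
  expect_equal(lowpass_filter(rep(3, 1000)), rep(3, 1000), tolerance = 1e-6)
  expect_error(lowpass_filter(slow, cutoff = -1), "cut-off")
  expect_error(lowpass_filter(slow, cutoff = 3.75, fs = 7), "twice")
})

test_that("the z-transform standardises with the population convention", {
  set.seed(13)
  x <- rnorm(1000, 5, 2)
  z <- z_transform(x)
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-6)
  expect_equal(z_transform(3 * x - 7), z, tolerance = 1e-9)
  expect_equal(z_transform(c(1, 3)), c(-1, 1), tolerance = 1e-12)
  expect_error(z_transform(rep(2, 10)), "zero variance")
})

test_that("epoch extraction baseline-corrects against the pre-outcome window", {
  fs <- 100
  n <- 2000
  markers <- data.frame(block = 1, trial = 1:2,
                        event_sample = c(300, 1100),
                        win_obtained = c(TRUE, FALSE),
                        loss_obtained = c(FALSE, TRUE))
  # constant trace: all-zero epochs
  ep0 <- extract_epochs(make_clean(rep(2, n), fs), markers)
  expect_true(all(ep0$samples == 0))
  expect_identical(nrow(ep0$meta), 4L)

  # step of height d at the first outcome: epoch constant at d
  d <- 1.5
  x <- rep(0, n)
  x[300:n] <- d
  ep <- extract_epochs(make_clean(x, fs), markers)
  expect_true(all(ep$samples[ep$meta$trial == 1, ] == d))

  # a marker without a complete window is excluded with reason "edge"
  m2 <- rbind(markers,
              data.frame(block = 1, trial = 3, event_sample = 1950,
                         win_obtained = TRUE, loss_obtained = FALSE))
  ep2 <- extract_epochs(make_clean(x, fs), m2)
  expect_true(all(!ep2$meta$included[ep2$meta$trial == 3]))
  expect_true(all(ep2$meta$reason[ep2$meta$trial == 3] == "edge"))

  # baseline means of corrected epochs recompute to zero
  set.seed(14)
  y <- rnorm(n)
  cl <- make_clean(y, fs)
  ep3 <- extract_epochs(cl, markers)
  for (i in 1:2) {
    on <- markers$event_sample[i]
    base <- mean(y[(on - fs):(on - 1)])
    expect_equal(ep3$samples[ep3$meta$trial == i, ][1, ],
                 y[on:(on + 6 * fs - 1)] - base, tolerance = 1e-9)
  }
})

test_that("trial exclusion rules apply the strict interpolation threshold", {
  fs <- 100
  n <- 20000
  interp <- rep(FALSE, n)
  markers <- data.frame(block = 1, trial = 1:12,
                        event_sample = 150 + (0:11) * 1500,
                        win_obtained = TRUE, loss_obtained = FALSE)
  # trial 11: 60% of the post window interpolated; trial 12: exactly 50%
  post11 <- markers$event_sample[11] + 0:(6 * fs - 1)
  post12 <- markers$event_sample[12] + 0:(6 * fs - 1)
  interp[post11[1:360]] <- TRUE
  interp[post12[1:300]] <- TRUE
  ep <- extract_epochs(make_clean(rnorm(n), fs, interp), markers)
  ep <- apply_exclusions(ep)
  m <- ep$meta
  expect_true(all(!m$included[m$trial <= 10]))
  expect_true(all(m$reason[m$trial <= 10] == "adaptation"))
  expect_true(all(!m$included[m$trial == 11]))
  expect_true(all(m$reason[m$trial == 11] == "interpolation"))
  expect_true(all(m$included[m$trial == 12]))

  # the adaptation cut keeps trial 11+ when interpolation is clean
  interp2 <- rep(FALSE, n)
  ep2 <- apply_exclusions(extract_epochs(make_clean(rnorm(n), fs, interp2),
                                         markers))
  expect_true(all(!ep2$meta$included[ep2$meta$trial == 10]))
  expect_true(all(ep2$meta$included[ep2$meta$trial == 11]))
})

test_that("participant-level exclusion uses the excluded-trial fraction", {
  fake <- function(frac, n = 200) {
    meta <- data.frame(block = 1, trial = rep(11:(10 + n), each = 2),
                       valence = rep(c("win", "loss"), n),
                       obtained = TRUE,
                       frac_interpolated = 0,
                       included = rep(rep(c(FALSE, TRUE),
                                          c(round(frac * n),
                                            n - round(frac * n))),
                                      each = 2),
                       reason = NA_character_)
    meta$reason[!meta$included] <- "interpolation"
    structure(list(meta = meta, samples = matrix(0, nrow(meta), 10),
                   fs = 500, post_s = 6),
              class = "pupil_epochs")
  }
  expect_true(exclude_participant(fake(0.995))$exclude)
  expect_false(exclude_participant(fake(0.07))$exclude)
  expect_false(exclude_participant(fake(0))$exclude)
})

test_that("difference timeseries subtracts unobtained from obtained", {
  n_post <- 600
  meta <- data.frame(block = 1, trial = rep(11:30, each = 2),
                     valence = rep(c("win", "loss"), 20),
                     obtained = rep(c(TRUE, FALSE), each = 20),
                     frac_interpolated = 0, included = TRUE,
                     reason = NA_character_)
  base <- matrix(rep(sin(seq(0, 3, length.out = n_post)), nrow(meta)),
                 nrow(meta), n_post, byrow = TRUE)
  ep <- structure(list(meta = meta, samples = base, fs = 100, post_s = 6),
                  class = "pupil_epochs")
  d0 <- difference_timeseries(ep)
  expect_true(all(abs(d0$bins$difference) < 1e-12))

  # obtained epochs offset by a constant d: every bin reads d
  d <- 0.8
  ep$samples[meta$obtained, ] <- ep$samples[meta$obtained, ] + d
  d1 <- difference_timeseries(ep)
  expect_equal(d1$bins$difference, rep(d, nrow(d1$bins)), tolerance = 1e-12)
  expect_equal(d1$mean6s$mean6s, rep(d, nrow(d1$mean6s)), tolerance = 1e-12)
  expect_identical(nrow(d1$bins), 12L)  # 1 block x 2 valences x 6 bins

  # an empty cell is flagged missing
  ep$meta$included[ep$meta$valence == "win" & ep$meta$obtained] <- FALSE
  d2 <- difference_timeseries(ep)
  expect_true(d2$mean6s$missing[d2$mean6s$valence == "win"])
})

test_that("filtering and z-scoring commute up to an affine map", {
  set.seed(15)
  x <- cumsum(rnorm(5000)) + rnorm(5000, sd = 3)
  a <- z_transform(lowpass_filter(x))
  b <- lowpass_filter(z_transform(x))
  fit <- lm(a ~ b)
  expect_gt(summary(fit)$r.squared, 1 - 1e-9)
})

test_that("synthetic traces embed the dilation kernel exactly", {
  sess <- data.frame(block = 1, trial = 1, choice = "A",
                     win_side = "A", loss_side = "B",
                     stringsAsFactors = FALSE)
  gen <- pupil_gen_params(noise_sd = 0, drift_amp = 0, blink_rate_hz = 0)
  ps <- simulate_pupil(sess, gen, seed = 91,
                       block_types = "both_volatile")
  expect_true(all(ps$trace$valid))
  on <- ps$markers$event_sample
  amp <- gen$base_amp_win + pupil_effect_spec()$win_volatile +
    gen$base_amp_loss  # win obtained, loss not
  kern_t <- seq(0, 6, by = 1 / gen$fs)
  kern <- dgamma(kern_t, shape = gen$kernel_shape, scale = gen$kernel_scale)
  kern <- kern / max(kern)
  got <- ps$trace$pupil[on:(on + length(kern) - 1)] - gen$baseline_level
  expect_equal(got, amp * kern, tolerance = 1e-12)
  expect_true(all(ps$trace$pupil[1:(on - 1)] == gen$baseline_level))
})

test_that("null effects and impossible amplitudes behave as specified", {
  sess <- generate_session("win_volatile_first", seed = 93)
  ag <- simulate_agent("m1",
                       list(alpha_win = 0.4, alpha_loss = 0.4,
                            beta_win = 5, beta_loss = 5),
                       sess, seed = 94)
  # zero injected effect in a deterministic trace: obtained and unobtained
  # epochs are identical, so the difference timeseries vanishes
  gen <- pupil_gen_params(noise_sd = 0, drift_amp = 0, blink_rate_hz = 0)
  null_spec <- pupil_effect_spec(0, 0, 0, 0)
  ps <- simulate_pupil(ag, gen, null_spec, seed = 95)
  pp <- preprocess_pupil(ps$trace, ps$markers)
  expect_true(all(abs(pp$difference$bins$difference) < 1e-6))

  # amplitudes that push pupil area non-positive are rejected
  bad <- pupil_gen_params(baseline_level = 0.2, base_amp_win = -2,
                          noise_sd = 0)
  expect_error(simulate_pupil(ag, bad, seed = 96), "non-positive")
})

test_that("every epoch is accounted for after the pipeline", {
  sess <- generate_session("loss_volatile_first", seed = 97)
  ag <- simulate_agent("m1",
                       list(alpha_win = 0.3, alpha_loss = 0.3,
                            beta_win = 4, beta_loss = 4),
                       sess, seed = 98)
  ps <- simulate_pupil(ag, seed = 99)
  pp <- preprocess_pupil(ps$trace, ps$markers)
  m <- pp$epochs$meta
  expect_identical(nrow(m), 2L * nrow(ps$markers))
  expect_true(all(xor(m$included, !is.na(m$reason))))
  expect_true(all(m$reason[!m$included] %in%
                    c("edge", "interpolation", "adaptation")))
  expect_identical(length(pp$clean$signal), nrow(ps$trace))
  expect_identical(sum(pp$clean$interpolated), sum(!ps$trace$valid))
})
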