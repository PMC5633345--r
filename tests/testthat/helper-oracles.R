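# Independent oracles used across the suite. Deliberately naive: plain
# loops and textbook formulas, no shared code with the package internals.

# Bernoulli choice log-likelihood from per-trial probabilities of choosing A.
oracle_loglik <- function(p_choose_A, choices, exclude_first = 10) {
  ll <- 0
  for (i in seq_along(choices)) {
    if (i <= exclude_first) next
    p <- if (choices[i] == "A") p_choose_A[i] else 1 - p_choose_A[i]
    ll <- ll + log(max(p, 1e-12))
  }
  ll
}

# Trial-by-trial m1 trajectory computed longhand.
oracle_m1_trajectory <- function(win_side, loss_side, aw, al, bw, bl) {
  n <- length(win_side)
  rw <- rl <- p <- numeric(n)
  cw <- cl <- 0.5
  for (i in seq_len(n)) {
    rw[i] <- cw; rl[i] <- cl
    p[i] <- 1 / (1 + exp(-(bw * cw - bl * cl)))
    cw <- cw + aw * ((win_side[i] == "A") - cw)
    cl <- cl + al * ((loss_side[i] == "A") - cl)
  }
  list(r_win = rw, r_loss = rl, p_choose_A = p)
}

# Mixed 2 (within) x 2 (within) x between ANOVA via per-subject contrast
# scores: each within effect is a difference score analysed by ordinary
# regression on the (balanced, effect-coded) group factor, the between
# effect an ANOVA on subject means. Valid for balanced two-level designs.
oracle_mixed_anova_2x2 <- function(d, dv = "y", subject = "participant",
                                   w1 = "w1", w2 = "w2", between = "g") {
  d[[w1]] <- factor(d[[w1]]); d[[w2]] <- factor(d[[w2]])
  ids <- unique(d[[subject]])
  cells <- t(vapply(ids, function(s) {
    ds <- d[d[[subject]] == s, ]
    c(y11 = ds[[dv]][ds[[w1]] == levels(d[[w1]])[1] &
                       ds[[w2]] == levels(d[[w2]])[1]],
      y12 = ds[[dv]][ds[[w1]] == levels(d[[w1]])[1] &
                       ds[[w2]] == levels(d[[w2]])[2]],
      y21 = ds[[dv]][ds[[w1]] == levels(d[[w1]])[2] &
                       ds[[w2]] == levels(d[[w2]])[1]],
      y22 = ds[[dv]][ds[[w1]] == levels(d[[w1]])[2] &
                       ds[[w2]] == levels(d[[w2]])[2]])
  }, numeric(4)))
  g <- factor(vapply(ids, function(s) {
    as.character(d[[between]][d[[subject]] == s][1])
  }, character(1)))
  gc <- ifelse(g == levels(g)[1], 1, -1)  # effect coding, balanced groups

  f_from_scores <- function(score) {
    fit <- lm(score ~ gc)
    tt <- summary(fit)$coefficients
    c(main = tt["(Intercept)", "t value"]^2, inter = tt["gc", "t value"]^2)
  }
  m <- rowMeans(cells)
  f_between <- anova(lm(m ~ g))[1, "F value"]
  f1 <- f_from_scores((cells[, "y21"] + cells[, "y22"] -
                         cells[, "y11"] - cells[, "y12"]) / 2)
  f2 <- f_from_scores((cells[, "y12"] + cells[, "y22"] -
                         cells[, "y11"] - cells[, "y21"]) / 2)
  f12 <- f_from_scores((cells[, "y22"] - cells[, "y21"] -
                          cells[, "y12"] + cells[, "y11"]) / 2)
  c(between = f_between,
    w1 = f1[["main"]], w1_between = f1[["inter"]],
    w2 = f2[["main"]], w2_between = f2[["inter"]],
    w1_w2 = f12[["main"]], w1_w2_between = f12[["inter"]])
}

# A deterministic minimal session schedule built by hand (no RNG), used for
# model-equation tests.
toy_schedule <- function(win_side, loss_side) {
  data.frame(trial = seq_along(win_side),
             p_win_A = 0.5, p_loss_A = 0.5,
             win_side = win_side, loss_side = loss_side,
             stringsAsFactors = FALSE)
}

# A factorial cohort table (2 within x 2 within x between) with an
# injected crossover interaction of the given size.
sim_cohort_table <- function(n = 8, interaction = 0, noise = 1, seed = 1) {
  set.seed(seed)
  d <- expand.grid(participant = seq_len(n),
                   block_vol = c("win_volatile", "loss_volatile"),
                   valence = c("win", "loss"),
                   stringsAsFactors = FALSE)
  d$block_order <- ifelse(d$participant <= n / 2, "win_first", "loss_first")
  cross <- ifelse((d$valence == "win") == (d$block_vol == "win_volatile"),
                  1, -1)
  d$y <- interaction / 2 * cross + rnorm(nrow(d), 0, noise)
  d
}

# Bernoulli draws under a local seed (leaves the global stream untouched).
with_seed_rbinom <- function(seed, n, p) {
  env <- globalenv()
  old <- if (exists(".Random.seed", env, inherits = FALSE)) {
    get(".Random.seed", env)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, env))
  set.seed(seed)
  rbinom(n, 1, p)
}

# Amplitude of a sinusoid recovered by least squares (edge-trimmed), for
# filter frequency-response measurements.
fitted_amplitude <- function(x, freq, fs) {
  n <- length(x)
  keep <- seq.int(round(n * 0.2), round(n * 0.8))
  t_s <- (keep - 1) / fs
  X <- cbind(sin(2 * pi * freq * t_s), cos(2 * pi * freq * t_s))
  cf <- coef(lm(x[keep] ~ X))
  sqrt(cf[2]^2 + cf[3]^2)
}
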