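#' Mixed repeated-measures ANOVA
#'
#' Classical univariate mixed-design ANOVA: any number of fully crossed
#' within-subject factors, at most one between-subject factor, one
#' observation per subject and within-cell. Sums of squares are decomposed
#' by `aov` with the appropriate within-subject error strata.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param within Character vector of within-subject factor columns.
#' @param between Optional name of a between-subject factor column.
#' @param gg Also report Greenhouse-Geisser corrected p-values for
#'   within-subject effects (useful when a within factor has more than two
#'   levels; default off).
#' @return Data frame of class `anova_table` with columns `effect`, `df1`,
#'   `df2`, `ss`, `F`, `p` (plus `epsilon`, `p_gg` when `gg = TRUE`).
#' @export
rm_anova_mixed <- function(data, dv, subject, within, between = NULL,
                           gg = FALSE) {
  data <- as.data.frame(data)
  for (f in c(subject, within, between)) data[[f]] <- factor(data[[f]])
  # Balance checks: one observation per subject x within cell, and at least
  # two subjects per between level.
  wcell <- interaction(data[c(subject, within)], drop = FALSE)
  counts <- table(wcell)
  if (any(counts != 1L)) {
    bad <- names(counts)[counts != 1L][1]
    stop("unbalanced design: cell ", bad, " has ", counts[counts != 1L][1],
         " observations (need exactly 1)")
  }
  if (!is.null(between)) {
    per_subj <- unique(data[c(subject, between)])
    if (any(table(per_subj[[between]]) < 2L)) {
      stop("each level of ", between, " needs at least 2 subjects")
    }
  }
  fx <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", subject, "/(", paste(within, collapse = " * "),
                "))")
  form <- stats::as.formula(paste(dv, "~", fx, "+", err))
  fit <- aov(form, data = data)
  sm <- summary(fit)

  rows <- list()
  for (stratum in sm) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    effs <- trimws(rownames(tab))
    resid_df <- tab$Df[effs == "Residuals"]
    for (i in seq_len(nrow(tab))) {
      if (effs[i] == "Residuals") next
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(" ", "", effs[i]),
        df1 = tab$Df[i],
        df2 = if (length(resid_df)) resid_df else NA_real_,
        ss = tab$`Sum Sq`[i],
        F = if ("F value" %in% names(tab)) tab$`F value`[i] else NA_real_,
        p = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)`[i] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)

  if (gg) {
    eps <- gg_epsilon(data, dv, subject, within, between)
    out$epsilon <- eps[out$effect]
    out$p_gg <- ifelse(is.na(out$epsilon), NA_real_,
                       stats::pf(out$F, out$df1 * out$epsilon,
                                 out$df2 * out$epsilon, lower.tail = FALSE))
  }
  # Record residual sums of squares so the partition can be audited.
  ss_resid <- sum(vapply(sm, function(stratum) {
    tab <- as.data.frame(if (is.list(stratum)) stratum[[1]] else stratum)
    sum(tab$`Sum Sq`[trimws(rownames(tab)) == "Residuals"])
  }, numeric(1)))
  attr(out, "ss_residuals") <- ss_resid
  class(out) <- c("anova_table", "data.frame")
  out
}

# Greenhouse-Geisser epsilon per within-subject effect, from the pooled
# within-group covariance of the subject x cell matrix projected onto each
# effect's orthonormal contrasts.
gg_epsilon <- function(data, dv, subject, within, between) {
  lev <- lapply(within, function(f) levels(data[[f]]))
  names(lev) <- within
  cells <- do.call(interaction, c(rev(data[within]), list(lex.order = FALSE)))
  wide <- tapply(data[[dv]], list(data[[subject]], cells), mean)
  if (is.null(between)) {
    S <- stats::cov(wide)
  } else {
    grp <- data[[between]][match(rownames(wide), data[[subject]])]
    parts <- lapply(split(seq_len(nrow(wide)), grp), function(ix) {
      (length(ix) - 1) * stats::cov(wide[ix, , drop = FALSE])
    })
    S <- Reduce(`+`, parts) / (nrow(wide) - length(parts))
  }
  effects <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, paste, collapse = ":", simplify = FALSE)
  }))
  eps <- setNames(rep(NA_real_, length(effects)), effects)
  for (e in effects) {
    fs <- strsplit(e, ":")[[1]]
    C <- 1
    for (f in rev(within)) {  # match cell (column) ordering
      l <- length(lev[[f]])
      M <- if (f %in% fs) {
        stats::contr.poly(l)
      } else {
        matrix(1 / sqrt(l), l, 1)
      }
      C <- kronecker(C, M)
    }
    Se <- t(C) %*% S %*% C
    d <- ncol(Se)
    eps[e] <- (sum(diag(Se)))^2 / (d * sum(Se^2))
  }
  eps
}

#' Recode block volatility to outcome volatility
#'
#' Maps the block label onto whether each row's own valence was volatile in
#' that block: wins are volatile in the win-volatile block, losses in the
#' loss-volatile block. Used for the test of whether the volatility effect
#' differs between valences.
#'
#' @param data Data frame with columns `valence` (`"win"`/`"loss"`) and
#'   `block_vol` (`"win_volatile"`/`"loss_volatile"`).
#' @return The data frame with an added `outcome_volatility` column
#'   (`"volatile"`/`"stable"`).
#' @export
recode_outcome_volatility <- function(data) {
  stopifnot(all(data$valence %in% c("win", "loss")),
            all(data$block_vol %in% c("win_volatile", "loss_volatile")))
  data$outcome_volatility <- ifelse(
    (data$valence == "win") == (data$block_vol == "win_volatile"),
    "volatile", "stable")
  data
}

#' Per-participant change scores between volatile and stable blocks
#'
#' For each participant and valence, the difference of the logit-transformed
#' learning rate between the block in which that valence was volatile and
#' the block in which it was stable, together with the matching difference
#' of the pupil 6 s mean obtained-vs-unobtained response. Because the
#' learning rates are transformed onto the real line first, the difference
#' can exceed +/-1.
#'
#' @param data Long data frame with columns `participant`, `valence`,
#'   `block_vol`, `alpha` (raw learning rate in (0,1)) and optionally
#'   `pupil` (6 s mean difference score).
#' @return Data frame with one row per participant x valence: `d_alpha`
#'   (logit difference) and, when pupil data are present, `d_pupil`.
#'   Participants missing either block are dropped with a message.
#' @export
change_scores <- function(data) {
  has_pupil <- "pupil" %in% names(data)
  out <- list()
  for (id in unique(data$participant)) {
    for (val in c("win", "loss")) {
      d <- data[data$participant == id & data$valence == val, ]
      vol_block <- paste0(val, "_volatile")
      v <- d[d$block_vol == vol_block, ]
      s <- d[d$block_vol != vol_block, ]
      if (nrow(v) != 1L || nrow(s) != 1L) {
        message("participant ", id, " missing a block for ", val,
                "; dropped")
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        participant = id, valence = val,
        d_alpha = qlogis(v$alpha) - qlogis(s$alpha),
        d_pupil = if (has_pupil) v$pupil - s$pupil else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `df` (`n - 2`), `p` (two-sided), `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), df = length(x) - 2L, p = ct$p.value,
       n = length(x))
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value.
#'
#' @param r1,r2 Correlation coefficients (|r| < 1).
#' @param n1,n2 Sample sizes (> 3).
#' @return List with `z` and `p`.
#' @export
fisher_compare <- function(r1, r2, n1, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  stopifnot(abs(r1) < 1, abs(r2) < 1)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Group-level analysis battery for a cohort
#'
#' Runs the standard set of group analyses on the two single-volatile
#' blocks: the block volatility x valence mixed ANOVA on logit learning
#' rates (with block order between subjects), the same ANOVA on pupil
#' difference scores (optionally with time bin as an additional within
#' factor), the outcome-volatility recoded ANOVA, the behaviour-pupil
#' change-score correlations per valence, and their Fisher r-to-z
#' comparison.
#'
#' @param behaviour Long data frame: `participant`, `block_order`,
#'   `valence`, `block_vol`, `alpha`.
#' @param pupil Optional long data frame: `participant`, `block_order`,
#'   `valence`, `block_vol`, `mean6s` and optionally `bin`/`difference`
#'   rows for the binned ANOVA.
#' @return List of `anova_table`s and correlation results.
#' @export
analyze_cohort <- function(behaviour, pupil = NULL) {
  behaviour$alpha_t <- qlogis(pmin(pmax(behaviour$alpha, 1e-6), 1 - 1e-6))
  res <- list()
  res$behaviour_anova <- rm_anova_mixed(
    behaviour, "alpha_t", "participant",
    within = c("block_vol", "valence"), between = "block_order")
  if (!is.null(pupil)) {
    p6 <- unique(pupil[c("participant", "block_order", "valence",
                         "block_vol", "mean6s")])
    res$pupil_anova <- rm_anova_mixed(
      p6, "mean6s", "participant",
      within = c("block_vol", "valence"), between = "block_order")
    p6o <- recode_outcome_volatility(p6)
    res$pupil_outcome_volatility_anova <- rm_anova_mixed(
      p6o, "mean6s", "participant",
      within = c("outcome_volatility", "valence"), between = "block_order")
    if ("bin" %in% names(pupil) && "difference" %in% names(pupil)) {
      res$pupil_binned_anova <- rm_anova_mixed(
        pupil, "difference", "participant",
        within = c("block_vol", "valence", "bin"), between = "block_order")
    }
    cs <- change_scores(merge(
      behaviour[c("participant", "valence", "block_vol", "alpha")],
      p6[c("participant", "valence", "block_vol", "mean6s")],
      by = c("participant", "valence", "block_vol")) |>
        (\(d) {names(d)[names(d) == "mean6s"] <- "pupil"; d})())
    res$change_scores <- cs
    cw <- cs[cs$valence == "win", ]
    cl <- cs[cs$valence == "loss", ]
    res$correlation_win <- correlate(cw$d_alpha, cw$d_pupil)
    res$correlation_loss <- correlate(cl$d_alpha, cl$d_pupil)
    res$fisher <- fisher_compare(res$correlation_loss$r,
                                 res$correlation_win$r,
                                 res$correlation_loss$n,
                                 res$correlation_win$n)
  }
  res
}
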