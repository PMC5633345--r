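#' Read and write task files
#'
#' Plain-text (CSV with header) readers and writers for the package's
#' on-disk formats: session schedules (`block,trial,p_win_A,p_loss_A,
#' win_side,loss_side`), trial/choice data (`block,trial,choice,win_side,
#' loss_side[,earnings_delta]`), pupil traces (`time_s,pupil,valid`), event
#' markers (`block,trial,event_sample,win_obtained,loss_obtained`) and fit
#' results (`participant,model,block,alpha_win,alpha_loss,beta_win,
#' beta_loss,gamma,loglik,n_trials,bic`; parameters a model lacks are left
#' empty).
#'
#' @param x Object to write (a `session_schedule` or data frame for
#'   [write_schedule()]; a trial data frame for [write_trials()]; a list of
#'   `model_fit`s or one `model_fit` for [write_fits()]).
#' @param path File path.
#' @name task_io
NULL

#' @rdname task_io
#' @export
write_schedule <- function(x, path) {
  df <- if (inherits(x, "session_schedule")) as.data.frame(x) else {
    x <- as.data.frame(x)
    if (!"block" %in% names(x)) x <- cbind(block = 1L, x)
    x
  }
  write.csv(df[c("block", "trial", "p_win_A", "p_loss_A", "win_side",
                 "loss_side")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname task_io
#' @export
read_schedule <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname task_io
#' @export
write_trials <- function(x, path) {
  keep <- intersect(c("block", "trial", "choice", "win_side", "loss_side",
                      "earnings_delta"), names(x))
  write.csv(as.data.frame(x)[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname task_io
#' @export
read_trials <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname task_io
#' @param trace,markers Trace and marker data frames (see
#'   [simulate_pupil()]).
#' @param trace_path,marker_path File paths for the trace and marker files.
#' @export
write_pupil <- function(trace, markers, trace_path, marker_path) {
  write.csv(trace, trace_path, row.names = FALSE, quote = FALSE)
  write.csv(markers, marker_path, row.names = FALSE, quote = FALSE)
  invisible(c(trace_path, marker_path))
}

#' @rdname task_io
#' @export
read_pupil <- function(trace_path, marker_path) {
  list(trace = read.csv(trace_path, stringsAsFactors = FALSE),
       markers = read.csv(marker_path, stringsAsFactors = FALSE))
}

fit_columns <- c("participant", "model", "block", "alpha_win", "alpha_loss",
                 "beta_win", "beta_loss", "gamma", "loglik", "n_trials",
                 "bic")

#' @rdname task_io
#' @export
write_fits <- function(x, path) {
  if (inherits(x, "model_fit")) x <- list(x)
  rows <- lapply(x, function(f) {
    base <- data.frame(participant = f$participant %||% NA,
                       model = f$variant, block = f$params$block)
    for (col in c("alpha_win", "alpha_loss", "beta_win", "beta_loss",
                  "gamma")) {
      src <- if (col == "beta_win" && f$variant %in% c("m2", "m4", "m5")) {
        "beta_single"
      } else if (col == "alpha_win" && f$variant == "m2") {
        "alpha_value"
      } else col
      base[[col]] <- if (src %in% names(f$params)) f$params[[src]] else NA
    }
    base$loglik <- f$loglik
    base$n_trials <- f$n
    base$bic <- f$bic
    base
  })
  df <- do.call(rbind, rows)[fit_columns]
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname task_io
#' @export
read_fits <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
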