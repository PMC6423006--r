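#' Convert event histories to counting-process (start, stop] data
#'
#' Expands each subject's history into one row per inter-event interval
#' plus a final censored row, in the start-stop format used by the fitters.
#' The time-dependent stratum of a row is 1 + the number of the subject's
#' events strictly before the row's start (i.e. the label of the event the
#' subject is currently at risk for), optionally capped at `poolStratumAt`
#' so that e.g. `poolStratumAt = 4` pools subjects with three or more prior
#' events into one stratum.
#'
#' @param histories either a cohort list (`subjects` data.frame with
#'   `id, x, z, c` and `events` data.frame with `id, time`) or a list of
#'   [event_history()] objects.
#' @param poolStratumAt positive integer cap on the stratum label, or `NULL`
#'   for no pooling.
#' @return data.frame of class `counting_data` with columns
#'   `id, start, stop, status, stratum, x, z`.
#' @examples
#' h <- event_history(1, x = 1, z = 0, c = 1, eventTimes = 0.5)
#' to_counting_data(list(h))
#' @export
to_counting_data <- function(histories, poolStratumAt = NULL) {
  if (is.list(histories) && !is.null(histories$subjects)) {
    cohort <- histories
  } else {
    stopifnot(all(vapply(histories, inherits, logical(1), "event_history")))
    cohort <- list(
      subjects = data.frame(
        id = vapply(histories, function(h) as.integer(h$subjectId), integer(1)),
        x = vapply(histories, function(h) h$x, numeric(1)),
        z = vapply(histories, function(h) h$z, numeric(1)),
        c = vapply(histories, function(h) h$c, numeric(1))),
      events = data.frame(
        id = rep(vapply(histories, function(h) as.integer(h$subjectId), integer(1)),
                 vapply(histories, function(h) length(h$eventTimes), integer(1))),
        time = unlist(lapply(histories, function(h) h$eventTimes))))
  }
  subj <- cohort$subjects
  ev <- cohort$events
  n <- nrow(subj)
  if (!is.null(poolStratumAt))
    stopifnot(length(poolStratumAt) == 1L, poolStratumAt >= 1)

  ## map event ids to subject row, keep events ordered within subject
  pos <- match(ev$id, subj$id)
  if (anyNA(pos)) stop("event with unknown subject id")
  o <- order(pos, ev$time)
  ev <- ev[o, , drop = FALSE]
  pos <- pos[o]
  if (any(ev$time > subj$c[pos] + 1e-12))
    stop("event time beyond the subject's censoring time")
  if (any(ev$time <= 0)) stop("event times must be positive")

  k <- tabulate(pos, nbins = n)              # events per subject
  reps <- k + 1L
  rowSubj <- rep(seq_len(n), reps)           # subject row per output row
  j <- sequence(reps)                        # interval index within subject
  off <- rep(cumsum(c(0L, k))[seq_len(n)], reps)
  isEvent <- j <= rep(k, reps)

  startv <- numeric(length(j))
  prior <- j > 1L
  startv[prior] <- ev$time[(off + j - 1L)[prior]]
  stopv <- numeric(length(j))
  stopv[isEvent] <- ev$time[(off + j)[isEvent]]
  stopv[!isEvent] <- subj$c[rowSubj[!isEvent]]

  stratum <- if (is.null(poolStratumAt)) j else pmin(j, as.integer(poolStratumAt))
  out <- data.frame(id = subj$id[rowSubj],
                    start = startv, stop = stopv,
                    status = as.integer(isEvent),
                    stratum = as.integer(stratum),
                    x = subj$x[rowSubj], z = subj$z[rowSubj])
  ## drop the degenerate trailing row of a subject whose last event is at c
  out <- out[out$start < out$stop | out$status == 1L, , drop = FALSE]
  if (any(out$start >= out$stop))
    stop("degenerate interval: tied event times within a subject?")
  rownames(out) <- NULL
  class(out) <- c("counting_data", "data.frame")
  out
}

#' Read / write counting-process data as CSV
#'
#' Header `id,start,stop,status,stratum,x[,z,...]`; numeric fields are
#' written with 17 significant digits so a round trip is lossless.
#'
#' @param data a `counting_data` data.frame.
#' @param file path to a CSV file.
#' @return `read_counting_csv` returns a `counting_data` data.frame.
#' @export
write_counting_csv <- function(data, file) {
  df <- as.data.frame(lapply(data, function(col)
    if (is.double(col)) format(col, digits = 17, trim = TRUE, scientific = FALSE)
    else col))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(data)
}

#' @rdname write_counting_csv
#' @export
read_counting_csv <- function(file) {
  out <- utils::read.csv(file)
  need <- c("id", "start", "stop", "status", "stratum")
  if (!all(need %in% names(out)))
    stop("counting CSV must have columns ", paste(need, collapse = ", "))
  class(out) <- c("counting_data", "data.frame")
  out
}
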