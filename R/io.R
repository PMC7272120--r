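#' Read and write behavioural session logs as CSV
#'
#' One row per event, columns \code{time_s,event,trial_id,amplitude_c}.
#' Events are \code{trial_stimulus} / \code{trial_catch} (time = onset),
#' \code{lick} and \code{reward}. Round trips are lossless to the printed
#' precision (1e-6 s).
#'
#' @param path File path.
#' @param log A \code{\link{session_log}}.
#' @return \code{read_session_log} returns a \code{session_log};
#'   \code{write_session_log} returns \code{path} invisibly. Session
#'   metadata (response window, lockout) is stored alongside in a JSON
#'   sidecar \code{<path>.meta.json} when available.
#' @export
write_session_log <- function(path, log) {
  stopifnot(inherits(log, "session_log"))
  tr <- log$trials
  ev <- rbind(
    data.frame(time_s = tr$onset_s,
               event = paste0("trial_", tr$type),
               trial_id = tr$trial_id, amplitude_c = tr$amplitude_c),
    data.frame(time_s = log$licks, event = "lick", trial_id = NA,
               amplitude_c = NA),
    data.frame(time_s = log$rewards, event = "reward", trial_id = NA,
               amplitude_c = NA)
  )
  ev <- ev[order(ev$time_s, ev$event != "lick"), ]
  ev$time_s <- sprintf("%.6f", ev$time_s)
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE, na = "")
  if (length(log$meta)) {
    meta <- log$meta[!vapply(log$meta, is.object, logical(1))]
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  ev <- utils::read.csv(path, na.strings = "")
  need <- c("time_s", "event", "trial_id", "amplitude_c")
  if (!all(need %in% names(ev))) {
    stop("session file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  is_trial <- startsWith(ev$event, "trial_")
  tr <- ev[is_trial, ]
  tr <- tr[order(tr$time_s), ]
  trials <- data.frame(trial_id = tr$trial_id,
                       type = sub("^trial_", "", tr$event),
                       onset_s = tr$time_s,
                       amplitude_c = tr$amplitude_c,
                       stringsAsFactors = FALSE)
  meta <- list()
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) meta <- jsonlite::read_json(meta_path)
  session_log(trials,
              licks = ev$time_s[ev$event == "lick"],
              rewards = ev$time_s[ev$event == "reward"],
              meta = meta)
}

#' Read and write spike trains as CSV
#'
#' Long format, columns \code{unit_id,spike_time_s}; unit spans are stored
#' in the unit-record JSON (\code{\link{write_units}}), so reading takes a
#' \code{span} argument.
#'
#' @param path File path.
#' @param trains List of \code{\link{spike_train}} objects.
#' @param span Recording span, seconds, applied to all read trains.
#' @return \code{read_spikes} returns a list of \code{spike_train}
#'   objects keyed by unit id.
#' @export
write_spikes <- function(path, trains) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr) {
    if (!length(tr$spike_times)) return(NULL)
    data.frame(unit_id = tr$unit_id,
               spike_time_s = sprintf("%.6f", tr$spike_times))
  }))
  if (is.null(df)) df <- data.frame(unit_id = integer(0),
                                    spike_time_s = character(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, span = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("unit_id", "spike_time_s") %in% names(df))) {
    stop("spikes file must have columns unit_id,spike_time_s",
         call. = FALSE)
  }
  lapply(split(df$spike_time_s, df$unit_id), function(st)
    spike_train(sort(st), span = span))
}

#' Read and write unit records as JSON
#'
#' @param path File path.
#' @param units Unit-record data.frame (see
#'   \code{\link{sample_population_units}}).
#' @return \code{read_units} returns the data.frame.
#' @export
write_units <- function(path, units) {
  jsonlite::write_json(units, path, dataframe = "rows", digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_units
#' @export
read_units <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
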