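#' Epochs tensor
#'
#' One participant's epoched EEG: a trials x channels x samples array with a
#' uniform millisecond time axis. Times follow the half-open storage
#' convention: an epoch covering -800..0 ms at 1,000 Hz is stored as the 800
#' samples -800, -799, ..., -1 ms.
#'
#' @param data Numeric array, trials x channels x samples, all finite.
#' @param times Numeric vector of sample times in ms, strictly increasing
#'   with a uniform step.
#' @param rate Sampling rate in Hz; must match the time step.
#' @param participant Participant identifier.
#' @param trials Character vector of sentence ids, one per trial.
#' @param channels Character vector of channel labels (default "ch01"...).
#' @return An object of class `epochs_tensor`.
#' @export
epochs_tensor <- function(data, times, rate, participant, trials,
                          channels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  dims <- dim(data)
  if (dims[2L] < 2L) stop("need at least two channels")
  if (!all(is.finite(data))) stop("epoch data must be finite")
  times <- as.numeric(times)
  if (length(times) != dims[3L]) stop("times must match the third dimension")
  if (length(times) > 1L) {
    steps <- diff(times)
    if (any(steps <= 0) || max(abs(steps - steps[1L])) > 1e-6) {
      stop("times must be strictly increasing with a uniform step")
    }
    if (abs(steps[1L] - 1000 / rate) > 1e-6) {
      stop("time step does not match the sampling rate")
    }
  }
  trials <- as.character(trials)
  if (length(trials) != dims[1L]) stop("one trial id per epoch required")
  if (anyDuplicated(trials)) stop("duplicate trial ids")
  channels <- channels %||% sprintf("ch%02d", seq_len(dims[2L]))
  structure(list(data = data, times = times, rate = rate,
                 participant = as.character(participant),
                 trials = trials, channels = as.character(channels)),
            class = "epochs_tensor")
}

#' @export
print.epochs_tensor <- function(x, ...) {
  cat(sprintf("<epochs_tensor> participant %s: %d trials x %d channels x %d samples, %g Hz, %g..%g ms\n",
              x$participant, length(x$trials), length(x$channels),
              length(x$times), x$rate, min(x$times), max(x$times)))
  invisible(x)
}

#' Crop an epochs tensor to a time window
#'
#' Keeps samples with `start_ms <= t <= end_ms` (both endpoints inclusive on
#' the stored grid). Idempotent when re-applied with the same window.
#'
#' @param epochs An [epochs_tensor()].
#' @param start_ms,end_ms Window bounds in ms, `start_ms < end_ms`.
#' @export
crop_window <- function(epochs, start_ms, end_ms) {
  stopifnot(inherits(epochs, "epochs_tensor"), start_ms < end_ms)
  keep <- epochs$times >= start_ms & epochs$times <= end_ms
  if (!any(keep)) stop("empty selection: no samples in [", start_ms, ", ", end_ms, "] ms")
  epochs_tensor(epochs$data[, , keep, drop = FALSE], epochs$times[keep],
                epochs$rate, epochs$participant, epochs$trials, epochs$channels)
}

#' Select channels by label
#'
#' Restricts an epochs tensor to a channel subset (e.g. scalp channels only,
#' excluding EOG/reference channels before pattern correlation).
#'
#' @param epochs An [epochs_tensor()].
#' @param channels Character vector of labels to keep, in tensor order.
#' @export
select_channels <- function(epochs, channels) {
  stopifnot(inherits(epochs, "epochs_tensor"))
  keep <- epochs$channels %in% channels
  if (sum(keep) < 2L) stop("channel selection leaves fewer than two channels")
  epochs_tensor(epochs$data[, keep, , drop = FALSE], epochs$times,
                epochs$rate, epochs$participant, epochs$trials,
                epochs$channels[keep])
}

#' Downsample an epochs tensor
#'
#' Polyphase resampling with a zero-phase anti-alias FIR filter (the
#' default), or plain subsampling for exactness checks. An -800..0 ms epoch
#' stored as 800 samples at 1,000 Hz yields 240 samples at 300 Hz.
#'
#' @param epochs An [epochs_tensor()].
#' @param target_rate Target sampling rate in Hz, below the current rate.
#' @param method `"resample"` (anti-aliased polyphase: zero-stuffing, a
#'   zero-phase FIR low-pass built from [signal::fir1()] applied with
#'   [signal::filtfilt()], then decimation) or `"subsample"`
#'   (nearest-sample decimation, no filtering; exact on already-smooth
#'   signals).
#' @export
downsample_epochs <- function(epochs, target_rate,
                              method = c("resample", "subsample")) {
  stopifnot(inherits(epochs, "epochs_tensor"))
  method <- match.arg(method)
  if (target_rate == epochs$rate) return(epochs)
  if (target_rate > epochs$rate) stop("target rate must not exceed the source rate")
  g <- gcd(target_rate, epochs$rate)
  p <- target_rate / g
  q <- epochs$rate / g
  if (abs(p - round(p)) > 1e-9 || abs(q - round(q)) > 1e-9) {
    stop("rates must form a rational resampling ratio")
  }
  p <- round(p); q <- round(q)
  n_in <- length(epochs$times)
  n_out <- floor(n_in * p / q)
  new_times <- epochs$times[1L] + (0:(n_out - 1L)) * (1000 / target_rate)
  dims <- dim(epochs$data)
  out <- array(0, dim = c(dims[1L], dims[2L], n_out))
  if (method == "subsample") {
    idx <- round((0:(n_out - 1L)) * q / p) + 1L
    out <- epochs$data[, , idx, drop = FALSE]
  } else {
    # polyphase: zero-stuff by p, zero-phase FIR low-pass at the target
    # Nyquist (filtfilt, so no group delay), keep every q-th sample
    taps <- as.numeric(signal::fir1(10L * max(p, q), 1 / q))
    pick <- seq(1L, by = q, length.out = n_out)
    stuff <- seq(1L, by = p, length.out = n_in)
    for (tr in seq_len(dims[1L])) for (ch in seq_len(dims[2L])) {
      up <- numeric(n_in * p)
      up[stuff] <- epochs$data[tr, ch, ] * p
      out[tr, ch, ] <- signal::filtfilt(taps, 1, up)[pick]
    }
  }
  epochs_tensor(out, new_times, target_rate, epochs$participant,
                epochs$trials, epochs$channels)
}

#' Write / read an epochs container
#'
#' One binary array per participant plus a JSON sidecar holding dimensions,
#' trial ids, channel labels, the time axis and sampling rate.
#'
#' @param epochs_list A list of [epochs_tensor()] objects.
#' @param dir Container directory (created if needed).
#' @export
write_epochs <- function(epochs_list, dir) {
  if (inherits(epochs_list, "epochs_tensor")) epochs_list <- list(epochs_list)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ep in epochs_list) {
    stopifnot(inherits(ep, "epochs_tensor"))
    base <- file.path(dir, ep$participant)
    con <- file(paste0(base, ".bin"), "wb")
    writeBin(as.numeric(ep$data), con, size = 8)
    close(con)
    meta <- list(participant = ep$participant, dims = dim(ep$data),
                 trials = ep$trials, channels = ep$channels,
                 times = ep$times, rate = ep$rate)
    jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' @rdname write_epochs
#' @param participants Optional subset of participant ids to read.
#' @export
read_epochs <- function(dir, participants = NULL) {
  sidecars <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (!length(sidecars)) stop("no epoch sidecars found in ", dir)
  out <- list()
  for (sc in sidecars) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(participants) && !meta$participant %in% participants) next
    bin <- sub("\\.json$", ".bin", sc)
    con <- file(bin, "rb")
    vals <- readBin(con, "numeric", n = prod(meta$dims), size = 8)
    close(con)
    out[[meta$participant]] <- epochs_tensor(
      array(vals, dim = meta$dims), meta$times, meta$rate,
      meta$participant, meta$trials, meta$channels)
  }
  out
}
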