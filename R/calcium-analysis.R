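# Calcium-trace analysis: ROI/neuropil trace extraction from movies,
# zero-phase low-pass filtering, neuropil compensation, robust transient
# detection, activity classification and cross-session fate taxonomies.

#' Extract ROI and neuropil traces from a movie
#'
#' The fluorescence of all pixels within each neuron's ROI (and, separately,
#' its neuropil mask) is averaged per frame.
#'
#' @param frames numeric array `frames x H x W`.
#' @param roi_masks integer label matrix `H x W`; label k marks neuron k's ROI.
#' @param neuropil_masks matching label matrix of neuropil annuli.
#' @return data.frame (`neuron_id`, `frame` (0-based), `f_roi`,
#'   `f_neuropil`), neurons labelled `n001`, `n002`, ... by mask label.
#' @export
extract_roi_traces <- function(frames, roi_masks, neuropil_masks) {
  abort_if(length(dim(frames)) != 3L, "frames must be a frames x H x W array")
  abort_if(!all(dim(frames)[2:3] == dim(roi_masks)) ||
             !all(dim(roi_masks) == dim(neuropil_masks)),
           "movie and mask dimensions disagree")
  labels <- sort(setdiff(unique(as.integer(roi_masks)), 0L))
  abort_if(length(labels) == 0L, "roi_masks contains no labels")
  n_frames <- dim(frames)[1L]
  flat <- matrix(frames, nrow = n_frames)  # frames x (H*W), column-major pixels
  out <- lapply(labels, function(k) {
    roi_idx <- which(as.integer(roi_masks) == k)
    np_idx <- which(as.integer(neuropil_masks) == k)
    abort_if(length(roi_idx) == 0L, "empty ROI mask for neuron %d", k)
    abort_if(length(np_idx) == 0L, "empty neuropil mask for neuron %d", k)
    data.frame(
      neuron_id = sprintf("n%03d", k),
      frame = 0:(n_frames - 1L),
      f_roi = rowMeans(flat[, roi_idx, drop = FALSE]),
      f_neuropil = rowMeans(flat[, np_idx, drop = FALSE]),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Zero-phase low-pass filter a fluorescence trace
#'
#' Second-order Butterworth low-pass applied forward and backward
#' (`signal::filtfilt`), so event onsets and peaks are not shifted in time.
#' The trace is extended at both ends by odd reflection before filtering and
#' trimmed afterwards, which confines startup transients to the discarded
#' padding; constant traces pass through unchanged.
#'
#' @param x numeric trace.
#' @param frame_rate_hz sampling rate (Hz).
#' @param cutoff_hz cutoff frequency (Hz); must be below the Nyquist
#'   frequency `frame_rate_hz / 2`.
#' @return the filtered trace (same length).
#' @export
lowpass_trace <- function(x, frame_rate_hz, cutoff_hz = 10) {
  abort_if(!is.numeric(x) || length(x) < 1L, "x must be a numeric trace")
  abort_if(cutoff_hz <= 0 || cutoff_hz >= frame_rate_hz / 2,
           "cutoff_hz must lie in (0, Nyquist); Nyquist is %g Hz",
           frame_rate_hz / 2)
  bf <- signal::butter(2, cutoff_hz / (frame_rate_hz / 2), type = "low")
  n <- length(x)
  if (n < 3L) return(x)
  pad <- min(n - 1L, max(60L, 10L * ceiling(frame_rate_hz / cutoff_hz)))
  head_pad <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Neuropil compensation of an ROI trace
#'
#' Subtracts the scaled neuropil trace and adds back the scaled neuropil
#' median over the whole session:
#' `f_comp = f_roi - alpha * f_neuropil + alpha * median(f_neuropil)`.
#' Adding any constant to `f_neuropil` leaves `f_comp` unchanged, and a
#' constant neuropil trace leaves `f_roi` untouched.
#'
#' @param f_roi,f_neuropil numeric traces of equal length.
#' @param alpha contamination coefficient (default 0.7).
#' @return the compensated trace.
#' @export
neuropil_compensate <- function(f_roi, f_neuropil, alpha = 0.7) {
  abort_if(length(f_roi) != length(f_neuropil),
           "f_roi and f_neuropil lengths differ (%d vs %d)",
           length(f_roi), length(f_neuropil))
  abort_if(alpha < 0, "alpha must be >= 0")
  # grouped as alpha * (f_neuropil - median) so a constant neuropil trace
  # leaves f_roi bitwise unchanged
  f_roi - alpha * (f_neuropil - stats::median(f_neuropil))
}

#' Detect calcium transients in a compensated trace
#'
#' The trace baseline is its median; the noise scale is the median absolute
#' deviation scaled to a Gaussian SD (`1.4826 * median(|x - median|)`).
#' A transient is a maximal run of at least `min_duration_frames` consecutive
#' frames above `baseline + k_sigma * sigma`. A neuron is active if it shows
#' at least one such transient; the frequency is events per minute of
#' recording. A constant trace (zero noise scale) yields zero events.
#'
#' @param x compensated fluorescence trace.
#' @param frame_rate_hz sampling rate (Hz).
#' @param min_duration_frames minimum supra-threshold run length (default 20
#'   frames, about 0.7 s at 30 Hz).
#' @param k_sigma threshold in robust noise SDs above baseline (default 3).
#' @return list of class `transient_train`: `events` (data.frame
#'   `start_frame`, `end_frame`, `peak_amplitude`; 0-based, half-open
#'   `[start, end)`), `n_events`, `frequency_per_min`, `active`,
#'   `baseline`, `sigma`, `threshold`, `n_frames`, `frame_rate_hz`.
#' @export
detect_transients <- function(x, frame_rate_hz, min_duration_frames = 20,
                              k_sigma = 3) {
  abort_if(length(x) < min_duration_frames,
           "trace shorter (%d) than min_duration_frames (%d)",
           length(x), min_duration_frames)
  baseline <- stats::median(x)
  sigma <- stats::mad(x, center = baseline)   # 1.4826 * median abs deviation
  events <- data.frame(start_frame = integer(), end_frame = integer(),
                       peak_amplitude = numeric())
  threshold <- baseline + k_sigma * sigma
  if (sigma > 0) {
    above <- x > threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_duration_frames
    if (any(keep)) {
      events <- data.frame(
        start_frame = starts[keep] - 1L,
        end_frame = ends[keep],          # half-open [start, end), 0-based
        peak_amplitude = mapply(function(a, b) max(x[a:b]) - baseline,
                                starts[keep], ends[keep])
      )
    }
  }
  n_events <- nrow(events)
  structure(
    list(events = events, n_events = n_events,
         frequency_per_min = 60 * n_events * frame_rate_hz / length(x),
         active = n_events >= 1L,
         baseline = baseline, sigma = sigma, threshold = threshold,
         n_frames = length(x), frame_rate_hz = frame_rate_hz),
    class = "transient_train"
  )
}

#' Classify a neuron's baseline activity level
#'
#' `"high"` at one or more transients per minute, `"low"` below one per
#' minute but with at least one event, `"inactive"` with no events.
#'
#' @param train a `transient_train` from [detect_transients()], or a
#'   frequency (per minute) with `n_events` inferred as `frequency > 0`.
#' @return one of `"high"`, `"low"`, `"inactive"`.
#' @export
classify_baseline_level <- function(train) {
  if (inherits(train, "transient_train")) {
    freq <- train$frequency_per_min
    n_ev <- train$n_events
  } else {
    freq <- as.numeric(train)
    n_ev <- as.integer(freq > 0)
  }
  if (n_ev == 0L) "inactive" else if (freq >= 1) "high" else "low"
}

#' Activity-fate taxonomy across baseline, mid and late sessions
#'
#' Two complementary taxonomies over per-neuron active flags at three
#' sessions (baseline, an early post-injury session, a late session):
#' \describe{
#'   \item{fate_from_baseline}{for neurons active at baseline:
#'     active-active-active is persistently active; active-silent-active
#'     regained; active-silent-silent silent at mid; active-active-silent
#'     silent at late only. Neurons inactive at baseline get `NA`.}
#'   \item{history_at_late}{for neurons active at the late session:
#'     persistently active if active at all three; regained if active at
#'     baseline but silent at mid; newly active if inactive at baseline.
#'     Neurons inactive at late get `NA`.}
#' }
#' Within each taxonomy the categories are mutually exclusive and exhaustive
#' over the relevant denominator.
#'
#' @param baseline,mid,late logical vectors of per-neuron active flags.
#' @param neuron_id optional neuron labels.
#' @return data.frame (`neuron_id`, `baseline`, `mid`, `late`,
#'   `fate_from_baseline`, `history_at_late`).
#' @export
classify_fate <- function(baseline, mid, late, neuron_id = NULL) {
  n <- length(baseline)
  abort_if(length(mid) != n || length(late) != n,
           "baseline, mid and late must have equal length")
  abort_if(anyNA(baseline) || anyNA(mid) || anyNA(late),
           "missing session activity flag")
  if (is.null(neuron_id)) neuron_id <- sprintf("n%03d", seq_len(n))
  b <- as.logical(baseline); m <- as.logical(mid); l <- as.logical(late)

  fate <- rep(NA_character_, n)
  fate[b & m & l] <- "persistently_active"
  fate[b & !m & l] <- "regained"
  fate[b & !m & !l] <- "silent_at_mid"
  fate[b & m & !l] <- "silent_at_late_only"

  hist <- rep(NA_character_, n)
  hist[l & b & m] <- "persistently_active"
  hist[l & b & !m] <- "regained"
  hist[l & !b] <- "newly_active"

  data.frame(neuron_id = neuron_id, baseline = b, mid = m, late = l,
             fate_from_baseline = fate, history_at_late = hist,
             stringsAsFactors = FALSE)
}

#' Fraction of active neurons
#'
#' @param active logical vector of per-neuron active flags for one
#'   population and session.
#' @return the fraction active (`#active / #neurons`).
#' @export
fraction_active <- function(active) {
  abort_if(length(active) == 0L, "empty neuron population")
  abort_if(anyNA(active), "missing activity flag")
  mean(as.logical(active))
}

#' Run the full per-neuron calcium analysis on a trace table
#'
#' Convenience wrapper chaining low-pass filtering, neuropil compensation and
#' transient detection over a long trace table, one neuron at a time.
#'
#' @param traces data.frame (`neuron_id`, `frame`, `f_roi`, `f_neuropil`).
#' @param frame_rate_hz sampling rate (Hz).
#' @param alpha neuropil compensation coefficient.
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param min_duration_frames,k_sigma transient-detection parameters, see
#'   [detect_transients()].
#' @return data.frame with one row per neuron: `neuron_id`, `n_events`,
#'   `frequency_per_min`, `active`, `level` (high/low/inactive).
#' @export
analyze_traces <- function(traces, frame_rate_hz, alpha = 0.7, cutoff_hz = 10,
                           min_duration_frames = 20, k_sigma = 3) {
  required <- c("neuron_id", "frame", "f_roi", "f_neuropil")
  abort_if(!all(required %in% names(traces)),
           "traces must have columns %s", paste(required, collapse = ", "))
  out <- lapply(split(traces, traces$neuron_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    filt <- lowpass_trace(tr$f_roi, frame_rate_hz, cutoff_hz)
    filt_np <- lowpass_trace(tr$f_neuropil, frame_rate_hz, cutoff_hz)
    comp <- neuropil_compensate(filt, filt_np, alpha)
    train <- detect_transients(comp, frame_rate_hz, min_duration_frames, k_sigma)
    data.frame(neuron_id = tr$neuron_id[1L], n_events = train$n_events,
               frequency_per_min = train$frequency_per_min,
               active = train$active,
               level = classify_baseline_level(train),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
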