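# Spike-to-fluorescence simulator: Poisson event trains convolved with a
# difference-of-exponentials indicator kernel, plus Gaussian shot noise and
# additive neuropil contamination constructed so that the median-recentred
# compensation formula used in the analysis layer is its exact inverse.

#' Parameters for the calcium-trace simulator
#'
#' Defaults emulate 10-minute resonant-scanner recordings: 30 Hz frame rate,
#' 18,000 frames, GCaMP6m-like kinetics (rise 0.08 s, decay 0.6 s). The event
#' amplitude and noise SD defaults give a peak signal-to-noise ratio of 10,
#' typical of somatic transients in layer II/III recordings.
#'
#' @param n_neurons number of neurons.
#' @param frame_rate_hz acquisition frame rate (Hz).
#' @param n_frames number of frames per recording.
#' @param event_rate_per_min Poisson rate of calcium events per minute.
#' @param kernel_rise_s,kernel_decay_s rise and decay time constants (s) of
#'   the difference-of-exponentials kernel; the kernel is normalised to unit
#'   peak so `event_amplitude` is the peak fluorescence added per event.
#' @param event_amplitude peak fluorescence amplitude per event (arbitrary
#'   intensity units, additive for overlapping events).
#' @param baseline resting fluorescence level added to every true trace.
#' @param noise_sd SD of i.i.d. Gaussian noise on the observed ROI trace.
#' @param neuropil_coefficient contamination coefficient alpha: the observed
#'   ROI trace receives `alpha * (f_neuropil - median(f_neuropil))`.
#' @param neuropil_baseline,neuropil_signal_sd level and SD of the slowly
#'   varying neuropil trace.
#' @param seed integer seed.
#' @return an object of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(n_neurons = 10,
                               frame_rate_hz = 30,
                               n_frames = 18000,
                               event_rate_per_min = 1.2,
                               kernel_rise_s = 0.08,
                               kernel_decay_s = 0.6,
                               event_amplitude = 1,
                               baseline = 1,
                               noise_sd = 0.1,
                               neuropil_coefficient = 0.7,
                               neuropil_baseline = 0.5,
                               neuropil_signal_sd = 0.2,
                               seed = 1L) {
  abort_if(!is.numeric(frame_rate_hz) || frame_rate_hz <= 0, "frame_rate_hz must be > 0")
  abort_if(!is_count(n_frames) || n_frames < 1, "n_frames must be >= 1")
  abort_if(!is_count(n_neurons) || n_neurons < 1, "n_neurons must be >= 1")
  abort_if(!is.numeric(event_rate_per_min) || event_rate_per_min < 0,
           "event_rate_per_min must be non-negative")
  abort_if(!is.numeric(neuropil_coefficient) || neuropil_coefficient < 0,
           "neuropil_coefficient must be >= 0")
  abort_if(kernel_rise_s <= 0 || kernel_decay_s <= 0 || kernel_rise_s >= kernel_decay_s,
           "kernel time constants must satisfy 0 < rise < decay")
  abort_if(noise_sd < 0 || neuropil_signal_sd < 0, "noise SDs must be non-negative")
  structure(
    list(n_neurons = as.integer(n_neurons), frame_rate_hz = frame_rate_hz,
         n_frames = as.integer(n_frames),
         event_rate_per_min = event_rate_per_min,
         kernel_rise_s = kernel_rise_s, kernel_decay_s = kernel_decay_s,
         event_amplitude = event_amplitude, baseline = baseline,
         noise_sd = noise_sd, neuropil_coefficient = neuropil_coefficient,
         neuropil_baseline = neuropil_baseline,
         neuropil_signal_sd = neuropil_signal_sd, seed = as.integer(seed)),
    class = "calcium_sim_params"
  )
}

# Difference-of-exponentials kernel sampled at the frame rate, unit peak.
calcium_kernel <- function(frame_rate_hz, rise_s, decay_s,
                           length_s = rise_s + 8 * decay_s) {
  t <- seq(0, length_s, by = 1 / frame_rate_hz)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

#' Simulate calcium recordings with known ground truth
#'
#' For each neuron a Poisson event train is drawn, convolved with the
#' indicator kernel and added to the baseline to give the ground-truth trace.
#' An independent neuropil trace is generated (smoothed Gaussian process) and
#' the observed ROI trace is
#' `true + alpha * (neuropil - median(neuropil)) + noise`. Because the
#' contamination term is recentred on the neuropil median, applying
#' [neuropil_compensate()] with the same alpha recovers the true trace
#' exactly when `noise_sd = 0`.
#'
#' @param params a [calcium_sim_params()] object.
#' @param movie if `TRUE`, additionally render a small movie: ROI disk pixels
#'   carry the observed trace, annulus pixels the neuropil trace.
#' @param movie_hw height/width in pixels of the rendered movie (square).
#' @return a list with
#'   \describe{
#'     \item{traces}{data.frame (`neuron_id`, `frame`, `f_roi`, `f_neuropil`);
#'       `frame` is 0-based.}
#'     \item{truth}{list with per-neuron `event_frames` (0-based frame of each
#'       event onset), `true_traces` (matrix frames x neurons) and the params.}
#'     \item{movie}{when requested, list of `frames` (array frames x H x W),
#'       `roi_masks` and `neuropil_masks` (integer label matrices, label k =
#'       neuron k).}
#'   }
#' @export
simulate_calcium_recording <- function(params, movie = FALSE, movie_hw = 64) {
  abort_if(!inherits(params, "calcium_sim_params"),
           "params must be created with calcium_sim_params()")
  set.seed(params$seed)
  n <- params$n_frames
  fr <- params$frame_rate_hz
  kern <- calcium_kernel(fr, params$kernel_rise_s, params$kernel_decay_s)
  rate_per_frame <- params$event_rate_per_min / 60 / fr

  ids <- sprintf("n%03d", seq_len(params$n_neurons))
  true_traces <- matrix(0, nrow = n, ncol = params$n_neurons,
                        dimnames = list(NULL, ids))
  obs <- matrix(0, nrow = n, ncol = params$n_neurons)
  npil <- matrix(0, nrow = n, ncol = params$n_neurons)
  event_frames <- vector("list", params$n_neurons)
  names(event_frames) <- ids

  for (j in seq_len(params$n_neurons)) {
    n_events <- stats::rpois(1L, rate_per_frame * n)
    onsets <- sort(sample.int(n, min(n_events, n), replace = FALSE))
    impulse <- numeric(n)
    impulse[onsets] <- params$event_amplitude
    sig <- if (length(onsets) > 0) {
      stats::convolve(impulse, rev(kern), type = "open")[seq_len(n)]
    } else numeric(n)
    true_traces[, j] <- params$baseline + sig
    # neuropil: smoothed white noise around its own baseline (slow shared
    # background fluctuations, independent of the somatic signal)
    raw_np <- stats::rnorm(n, 0, params$neuropil_signal_sd)
    win <- max(1L, as.integer(fr / 2))
    smooth_np <- stats::filter(raw_np, rep(1 / win, win), sides = 2)
    smooth_np[is.na(smooth_np)] <- 0
    npil[, j] <- params$neuropil_baseline + as.numeric(smooth_np)
    contamination <- params$neuropil_coefficient *
      (npil[, j] - stats::median(npil[, j]))
    noise <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd) else 0
    obs[, j] <- true_traces[, j] + contamination + noise
    event_frames[[j]] <- onsets - 1L   # 0-based
  }

  traces <- data.frame(
    neuron_id = rep(ids, each = n),
    frame = rep(0:(n - 1L), times = params$n_neurons),
    f_roi = as.numeric(obs),
    f_neuropil = as.numeric(npil),
    stringsAsFactors = FALSE
  )
  out <- list(traces = traces,
              truth = list(event_frames = event_frames,
                           true_traces = true_traces,
                           params = params))
  if (movie) out$movie <- render_calcium_movie(obs, npil, movie_hw)
  out
}

# Paint per-neuron disk ROIs and surrounding annulus neuropil masks onto a
# small square frame; non-mask pixels are zero.
render_calcium_movie <- function(obs, npil, hw) {
  n_neurons <- ncol(obs)
  n_frames <- nrow(obs)
  grid_n <- ceiling(sqrt(n_neurons))
  cell <- hw / grid_n
  r_roi <- max(1.5, cell * 0.18)
  r_np_in <- r_roi + 1
  r_np_out <- min(cell / 2 - 0.5, r_np_in + max(1.5, cell * 0.12))
  abort_if(r_np_out <= r_np_in,
           "movie_hw too small for %d neurons; increase movie_hw", n_neurons)
  xs <- matrix(rep(seq_len(hw), each = hw), nrow = hw)
  ys <- matrix(rep(seq_len(hw), times = hw), nrow = hw)
  roi_masks <- matrix(0L, hw, hw)
  np_masks <- matrix(0L, hw, hw)
  for (j in seq_len(n_neurons)) {
    gx <- (j - 1L) %% grid_n
    gy <- (j - 1L) %/% grid_n
    cx <- gx * cell + cell / 2
    cy <- gy * cell + cell / 2
    d2 <- (xs - cx)^2 + (ys - cy)^2
    roi_masks[d2 <= r_roi^2] <- j
    np_masks[d2 > r_np_in^2 & d2 <= r_np_out^2] <- j
  }
  frames <- array(0, dim = c(n_frames, hw, hw))
  for (j in seq_len(n_neurons)) {
    roi_idx <- which(roi_masks == j)
    np_idx <- which(np_masks == j)
    for (t in seq_len(n_frames)) {
      fr <- frames[t, , ]
      fr[roi_idx] <- obs[t, j]
      fr[np_idx] <- npil[t, j]
      frames[t, , ] <- fr
    }
  }
  list(frames = frames, roi_masks = roi_masks, neuropil_masks = np_masks)
}
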