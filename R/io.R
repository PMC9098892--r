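# File formats: long-format CSV tables (spine tracks, traces, tracing
# counts), multi-page TIFF movies with label-image masks, YAML run configs
# and JSON ground-truth sidecars. All CSVs are comma-separated with a header
# row and '.' decimal, independent of locale.

spine_track_columns <- c("animal_id", "dendrite_id", "dendrite_length_um",
                         "spine_id", "session", "present", "morph_type")

#' Read and validate a spine-tracking table
#'
#' @param path CSV file with columns `animal_id`, `dendrite_id`,
#'   `dendrite_length_um`, `spine_id`, `session`, `present`, `morph_type`.
#' @return validated data.frame.
#' @export
read_spine_tracks <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(spine_track_columns, names(tab))
  abort_if(length(missing) > 0, "%s: missing column(s): %s", path,
           paste(missing, collapse = ", "))
  tab$present <- as.integer(tab$present)
  bad <- which(!tab$present %in% c(0L, 1L))
  abort_if(length(bad) > 0, "%s: 'present' must be 0/1 (first bad row: %d)",
           path, bad[1L])
  tab$morph_type <- as.character(tab$morph_type)
  tab$morph_type[!is.na(tab$morph_type) & tab$morph_type == ""] <- NA_character_
  validate_spine_tracks(tab)
  tab[spine_track_columns]
}

#' Write a spine-tracking table
#'
#' Inverse of [read_spine_tracks()]; the write/read round-trip is the
#' identity on canonical tables.
#'
#' @param table spine-tracking data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_spine_tracks <- function(table, path) {
  validate_spine_tracks(table)
  utils::write.csv(table[spine_track_columns], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read a fluorescence trace table
#'
#' @param path CSV file with columns `neuron_id`, `frame`, `f_roi`,
#'   `f_neuropil`.
#' @return validated data.frame, ordered by neuron then frame.
#' @export
read_traces <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("neuron_id", "frame", "f_roi", "f_neuropil")
  missing <- setdiff(required, names(tab))
  abort_if(length(missing) > 0, "%s: missing column(s): %s", path,
           paste(missing, collapse = ", "))
  tab[order(tab$neuron_id, tab$frame), required]
}

#' Write a fluorescence trace table
#' @param traces data.frame (`neuron_id`, `frame`, `f_roi`, `f_neuropil`).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces[, c("neuron_id", "frame", "f_roi", "f_neuropil")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated movie as multi-page TIFF plus mask label images
#'
#' Frames are scaled into `[0, 1]` by the global maximum and written as
#' 16-bit TIFF; the scale factor is stored in a JSON sidecar so intensities
#' can be restored up to 16-bit quantisation. Masks are written as 16-bit
#' label images.
#'
#' @param movie list as produced by [simulate_calcium_recording()]'s
#'   `movie` element (`frames`, `roi_masks`, `neuropil_masks`).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly. Files: `movie.tif`, `roi_masks.tif`,
#'   `neuropil_masks.tif`, `movie_meta.json`.
#' @export
write_movie <- function(movie, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(movie$frames, 1e-12)
  pages <- lapply(seq_len(dim(movie$frames)[1L]),
                  function(t) movie$frames[t, , ] / scale)
  tiff::writeTIFF(pages, file.path(dir, "movie.tif"), bits.per.sample = 16L)
  write_mask <- function(m, f) {
    tiff::writeTIFF(m / 65535, file.path(dir, f), bits.per.sample = 16L)
  }
  write_mask(movie$roi_masks, "roi_masks.tif")
  write_mask(movie$neuropil_masks, "neuropil_masks.tif")
  jsonlite::write_json(list(intensity_scale = scale,
                            n_frames = dim(movie$frames)[1L],
                            height = dim(movie$frames)[2L],
                            width = dim(movie$frames)[3L]),
                       file.path(dir, "movie_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a movie directory written by [write_movie()]
#'
#' @param dir directory holding `movie.tif`, the mask TIFFs and the metadata
#'   sidecar.
#' @return list (`frames`, `roi_masks`, `neuropil_masks`) with intensities
#'   restored to the original scale (up to 16-bit quantisation).
#' @export
read_movie <- function(dir) {
  meta_path <- file.path(dir, "movie_meta.json")
  abort_if(!file.exists(meta_path), "no movie_meta.json in %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "movie.tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(length(pages), dim(pages[[1L]])))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]] * meta$intensity_scale
  read_mask <- function(f) {
    m <- tiff::readTIFF(file.path(dir, f))
    matrix(as.integer(round(m * 65535)), nrow = nrow(m))
  }
  roi <- read_mask("roi_masks.tif")
  np <- read_mask("neuropil_masks.tif")
  abort_if(!all(dim(frames)[2:3] == dim(roi)),
           "mask dimensions do not match the movie frames")
  labels <- setdiff(unique(as.integer(roi)), 0L)
  orphan <- setdiff(labels, unique(as.integer(np)))
  abort_if(length(orphan) > 0, "ROI label(s) without neuropil mask: %s",
           paste(orphan, collapse = ", "))
  list(frames = frames, roi_masks = roi, neuropil_masks = np)
}

#' Read tracing count and starter tables
#'
#' @param counts_path CSV (`brain_id`, `region`, `hemisphere`,
#'   `presyn_count`).
#' @param starters_path CSV (`brain_id`, `group`, `starter_counted`,
#'   `sections_imaged`, `sections_total`).
#' @return list (`counts`, `starters`), validated.
#' @export
read_tracing_tables <- function(counts_path, starters_path) {
  counts <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  starters <- utils::read.csv(starters_path, stringsAsFactors = FALSE)
  req_c <- c("brain_id", "region", "hemisphere", "presyn_count")
  req_s <- c("brain_id", "group", "starter_counted", "sections_imaged",
             "sections_total")
  abort_if(!all(req_c %in% names(counts)), "%s: missing column(s): %s",
           counts_path, paste(setdiff(req_c, names(counts)), collapse = ", "))
  abort_if(!all(req_s %in% names(starters)), "%s: missing column(s): %s",
           starters_path,
           paste(setdiff(req_s, names(starters)), collapse = ", "))
  list(counts = counts, starters = starters)
}

#' Read a pipeline run configuration
#'
#' @param path YAML file; see [default_run_config()] for the recognised keys.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(utils::modifyList(default_run_config(), cfg))
}

#' Default pipeline configuration
#'
#' Session order and baseline labels for the 3-day imaging schedule,
#' detection parameters (k_sigma, minimum transient duration, low-pass
#' cutoff, neuropil alpha) and bootstrap settings, plus the simulation sizes
#' used by [run_pipeline()].
#'
#' @return a named list of defaults; override any entry via the YAML config
#'   or [utils::modifyList()].
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    session_order = c("B1", "B2", "3d", "6d", "9d", "12d"),
    baseline_sessions = c("B1", "B2"),
    persistence_denominator = "post_baseline",
    spine_sim = list(n_dendrites = 30, spines_per_dendrite_mean = 60,
                     dendrite_length_um = 63,
                     elimination_prob = 0.08, formation_rate = 0.08),
    calcium_sim = list(n_neurons = 24, n_frames = 6000, frame_rate_hz = 30,
                       event_rate_per_min = 1.2),
    detection = list(k_sigma = 3, min_duration_frames = 20, cutoff_hz = 10,
                     alpha = 0.7),
    bootstrap = list(n_iterations = 10000, level = 0.95, unit = "neuron"),
    tracing_sim = list(n_brains = 6, n_starters_true = 90,
                       sections_imaged = 6, sections_total = 18)
  )
}

validate_run_config <- function(cfg) {
  abort_if(!all(cfg$baseline_sessions %in% cfg$session_order),
           "baseline_sessions must be a subset of session_order")
  det <- cfg$detection
  abort_if(det$k_sigma <= 0, "k_sigma must be > 0")
  abort_if(det$min_duration_frames < 1, "min_duration_frames must be >= 1")
  abort_if(det$alpha < 0, "alpha must be >= 0")
  abort_if(cfg$bootstrap$level <= 0 || cfg$bootstrap$level >= 1,
           "bootstrap level must lie in (0, 1)")
  abort_if(!cfg$persistence_denominator %in% c("post_baseline", "all_sessions"),
           "persistence_denominator must be post_baseline or all_sessions")
  cfg
}

#' Hash a configuration for run reports
#'
#' MD5 of the canonical YAML serialisation; changes whenever any parameter
#' changes.
#'
#' @param cfg a config list.
#' @return hex digest string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}
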