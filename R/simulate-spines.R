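# Synthetic longitudinal spine-tracking data: a discrete-time birth-death
# process over imaging sessions with session-specific elimination and
# formation hazards, mirroring the statistics the analysis layer estimates.

#' Parameters for the spine birth-death simulator
#'
#' @param n_dendrites number of dendritic stretches to simulate.
#' @param spines_per_dendrite_mean expected initial spine count per dendrite
#'   (initial counts are Poisson-distributed around this mean).
#' @param dendrite_length_um dendritic stretch length in micrometres. The
#'   default (63 um) matches typical apical-tuft stretches followed in vivo.
#' @param session_times ordered character vector of session labels. Default is
#'   two baselines three days apart followed by imaging every 3 days to 42d.
#' @param elimination_prob per-session probability that a spine present at the
#'   previous session is eliminated. Either a single value recycled to all
#'   post-first sessions or a named vector over `session_times[-1]`.
#' @param formation_rate per-session expected number of newly formed spines
#'   per spine present at the previous session (same recycling rules).
#' @param morph_type_probs named probability simplex over
#'   `c("mushroom", "thin", "stubby")` used to draw a morphology label for
#'   each spine at each session it is present.
#' @param reappearance logical; if `FALSE` (default) an eliminated spine never
#'   reappears under its own identity, so presence codes contain no 1,0,1
#'   pattern. If `TRUE`, eliminated spines may reappear with probability
#'   `formation_rate` at each later session (the analysis layer counts any
#'   0 to 1 step as a formation either way).
#' @param seed integer seed; the generator is fully reproducible.
#' @return an object of class `spine_sim_params`.
#' @export
spine_sim_params <- function(n_dendrites = 81,
                             spines_per_dendrite_mean = 126,
                             dendrite_length_um = 63,
                             session_times = c("B1", "B2", "3d", "6d", "9d",
                                               "12d", "15d", "18d", "21d",
                                               "24d", "27d", "30d", "33d",
                                               "36d", "39d", "42d"),
                             elimination_prob = 0.08,
                             formation_rate = 0.08,
                             morph_type_probs = c(mushroom = 0.55, thin = 0.3,
                                                  stubby = 0.15),
                             reappearance = FALSE,
                             seed = 1L) {
  abort_if(!is_count(n_dendrites) || n_dendrites < 1, "n_dendrites must be a positive count")
  abort_if(!is.numeric(spines_per_dendrite_mean) || spines_per_dendrite_mean < 0,
           "spines_per_dendrite_mean must be non-negative")
  abort_if(!is.numeric(dendrite_length_um) || dendrite_length_um <= 0,
           "dendrite_length_um must be positive")
  abort_if(length(session_times) < 2L, "at least 2 sessions are required")
  abort_if(anyDuplicated(session_times) > 0L, "session labels must be unique")

  transitions <- session_times[-1L]
  e <- expand_session_param(elimination_prob, transitions, "elimination_prob")
  f <- expand_session_param(formation_rate, transitions, "formation_rate")
  abort_if(!is_prob(e), "elimination_prob values must lie in [0, 1]")
  abort_if(any(f < 0), "formation_rate values must be non-negative")
  abort_if(!is_prob(morph_type_probs) ||
             abs(sum(morph_type_probs) - 1) > 1e-12 ||
             is.null(names(morph_type_probs)),
           "morph_type_probs must be a named simplex summing to 1")

  structure(
    list(n_dendrites = as.integer(n_dendrites),
         spines_per_dendrite_mean = spines_per_dendrite_mean,
         dendrite_length_um = dendrite_length_um,
         session_times = as.character(session_times),
         elimination_prob = e,
         formation_rate = f,
         morph_type_probs = morph_type_probs,
         reappearance = isTRUE(reappearance),
         seed = as.integer(seed)),
    class = "spine_sim_params"
  )
}

expand_session_param <- function(x, transitions, what) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- stats::setNames(rep(as.numeric(x), length(transitions)), transitions)
  }
  abort_if(is.null(names(x)) || !all(transitions %in% names(x)),
           "%s must be a single value or named over every post-first session", what)
  x[transitions]
}

#' Simulate longitudinal spine-tracking tables
#'
#' Generates a long-format per-spine presence table across imaging sessions.
#' Every spine present at session t-1 survives to session t with probability
#' `1 - e_t`; the number of newly formed spines at t is Poisson with mean
#' `f_t * N_(t-1)` where `N_(t-1)` is the dendrite's previous spine count, so
#' that the per-previous-total formation-rate estimator is unbiased for
#' `100 * f_t`. Spines are exchangeable along the dendrite (no spatial
#' structure is modelled).
#'
#' @param params a [spine_sim_params()] object.
#' @return a list with elements
#'   \describe{
#'     \item{tracks}{long-format data.frame with columns `animal_id`,
#'       `dendrite_id`, `dendrite_length_um`, `spine_id`, `session`,
#'       `present` (0/1) and `morph_type` (label when present, `NA` when
#'       absent). A spine has rows only from its birth session on.}
#'     \item{truth}{list with the per-transition hazards
#'       (`elimination_prob`, `formation_rate`), `session_times` and the seed.}
#'   }
#' @export
#' @examples
#' p <- spine_sim_params(n_dendrites = 3, spines_per_dendrite_mean = 10,
#'                       session_times = c("B1", "B2", "3d"), seed = 42)
#' sim <- simulate_spine_tracks(p)
#' head(sim$tracks)
simulate_spine_tracks <- function(params) {
  abort_if(!inherits(params, "spine_sim_params"),
           "params must be created with spine_sim_params()")
  set.seed(params$seed)
  sessions <- params$session_times
  n_sess <- length(sessions)
  morph_levels <- names(params$morph_type_probs)

  per_dendrite <- vector("list", params$n_dendrites)
  for (d in seq_len(params$n_dendrites)) {
    n0 <- stats::rpois(1L, params$spines_per_dendrite_mean)
    # presence matrix grows as spines are born; row = spine, col = session
    pres <- matrix(0L, nrow = n0, ncol = n_sess)
    if (n0 > 0) pres[, 1L] <- 1L
    birth <- rep(1L, n0)
    for (t in 2L:n_sess) {
      e_t <- params$elimination_prob[[t - 1L]]
      f_t <- params$formation_rate[[t - 1L]]
      alive_prev <- which(pres[, t - 1L] == 1L)
      n_prev <- length(alive_prev)
      if (n_prev > 0) {
        survives <- stats::runif(n_prev) >= e_t
        pres[alive_prev[survives], t] <- 1L
      }
      if (params$reappearance) {
        gone <- which(pres[, t - 1L] == 0L & birth < t)
        if (length(gone) > 0) {
          back <- stats::runif(length(gone)) < f_t
          pres[gone[back], t] <- 1L
        }
      }
      n_new <- stats::rpois(1L, f_t * n_prev)
      if (n_new > 0) {
        add <- matrix(0L, nrow = n_new, ncol = n_sess)
        add[, t] <- 1L
        pres <- rbind(pres, add)
        birth <- c(birth, rep(t, n_new))
      }
    }
    n_spines <- nrow(pres)
    if (n_spines == 0L) next
    # long format: rows only from birth session on
    rows <- lapply(seq_len(n_spines), function(s) {
      keep <- birth[s]:n_sess
      data.frame(
        dendrite_id = sprintf("d%03d", d),
        spine_id = sprintf("d%03d_s%04d", d, s),
        session = sessions[keep],
        present = pres[s, keep],
        stringsAsFactors = FALSE
      )
    })
    per_dendrite[[d]] <- do.call(rbind, rows)
  }
  tracks <- do.call(rbind, per_dendrite)
  if (is.null(tracks)) {
    tracks <- data.frame(dendrite_id = character(), spine_id = character(),
                         session = character(), present = integer(),
                         stringsAsFactors = FALSE)
  }
  n_row <- nrow(tracks)
  tracks$morph_type <- NA_character_
  if (n_row > 0) {
    present_idx <- which(tracks$present == 1L)
    tracks$morph_type[present_idx] <- sample(
      morph_levels, length(present_idx), replace = TRUE,
      prob = params$morph_type_probs)
  }
  tracks$animal_id <- "a01"
  tracks$dendrite_length_um <- params$dendrite_length_um
  tracks <- tracks[, c("animal_id", "dendrite_id", "dendrite_length_um",
                       "spine_id", "session", "present", "morph_type")]
  rownames(tracks) <- NULL

  list(tracks = tracks,
       truth = list(elimination_prob = params$elimination_prob,
                    formation_rate = params$formation_rate,
                    session_times = sessions,
                    seed = params$seed))
}
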