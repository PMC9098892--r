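# Synthetic monosynaptic-tracing experiments: region-specific Poisson
# presynaptic counts plus binomially thinned starter-cell observations.

#' Parameters for the tracing-count simulator
#'
#' @param regions character vector of brain-region labels.
#' @param mean_presyn_per_region named numeric vector (over `regions`) of
#'   expected presynaptic counts per brain.
#' @param hemisphere optional named character vector tagging each region
#'   `"contralesional"` or `"ipsilesional"`; defaults to contralesional.
#' @param n_starters_true true whole-brain starter-cell count.
#' @param sections_imaged,sections_total sections counted vs total sections
#'   in the series; observed starters are a binomial thinning of
#'   `n_starters_true` with probability `sections_imaged / sections_total`.
#' @param n_brains number of replicate brains.
#' @param group group label attached to every brain.
#' @param seed integer seed.
#' @return an object of class `tracing_sim_params`.
#' @export
tracing_sim_params <- function(regions = c("somatosensory", "motor",
                                           "auditory", "retrosplenial",
                                           "thalamus"),
                               mean_presyn_per_region = c(somatosensory = 800,
                                                          motor = 300,
                                                          auditory = 150,
                                                          retrosplenial = 120,
                                                          thalamus = 200),
                               hemisphere = NULL,
                               n_starters_true = 90,
                               sections_imaged = 6,
                               sections_total = 18,
                               n_brains = 6,
                               group = "control_7d",
                               seed = 1L) {
  abort_if(length(regions) < 1L, "at least one region is required")
  abort_if(is.null(names(mean_presyn_per_region)) ||
             !all(regions %in% names(mean_presyn_per_region)),
           "mean_presyn_per_region must be named over every region")
  abort_if(any(mean_presyn_per_region < 0), "mean presynaptic counts must be >= 0")
  abort_if(!is_count(n_starters_true), "n_starters_true must be a count")
  abort_if(!is_count(sections_imaged) || sections_imaged < 1,
           "sections_imaged must be >= 1")
  abort_if(!is_count(sections_total) || sections_imaged > sections_total,
           "sections_imaged must be <= sections_total")
  if (is.null(hemisphere)) {
    hemisphere <- stats::setNames(rep("contralesional", length(regions)), regions)
  }
  abort_if(!all(regions %in% names(hemisphere)),
           "hemisphere must be named over every region")
  structure(
    list(regions = as.character(regions),
         mean_presyn_per_region = mean_presyn_per_region[regions],
         hemisphere = hemisphere[regions],
         n_starters_true = as.integer(n_starters_true),
         sections_imaged = as.integer(sections_imaged),
         sections_total = as.integer(sections_total),
         n_brains = as.integer(n_brains),
         group = group, seed = as.integer(seed)),
    class = "tracing_sim_params"
  )
}

#' Simulate a monosynaptic-tracing experiment
#'
#' Per brain, each region's presynaptic count is Poisson with its configured
#' mean, and the observed starter count is a binomial thinning of the true
#' whole-brain starter count with sampling fraction
#' `sections_imaged / sections_total`, so starter interpolation (scaling back
#' by the inverse fraction) is unbiased for the true count.
#'
#' @param params a [tracing_sim_params()] object.
#' @return a list with
#'   \describe{
#'     \item{counts}{data.frame (`brain_id`, `region`, `hemisphere`,
#'       `presyn_count`).}
#'     \item{starters}{data.frame (`brain_id`, `group`, `starter_counted`,
#'       `sections_imaged`, `sections_total`).}
#'     \item{truth}{the params, including true per-region means and
#'       `n_starters_true`.}
#'   }
#' @export
simulate_tracing_experiment <- function(params) {
  abort_if(!inherits(params, "tracing_sim_params"),
           "params must be created with tracing_sim_params()")
  set.seed(params$seed)
  brains <- sprintf("%s_b%02d", params$group, seq_len(params$n_brains))
  frac <- params$sections_imaged / params$sections_total
  counts <- do.call(rbind, lapply(brains, function(b) {
    data.frame(brain_id = b,
               region = params$regions,
               hemisphere = unname(params$hemisphere),
               presyn_count = stats::rpois(length(params$regions),
                                           params$mean_presyn_per_region),
               stringsAsFactors = FALSE)
  }))
  starters <- data.frame(
    brain_id = brains,
    group = params$group,
    starter_counted = stats::rbinom(params$n_brains, params$n_starters_true, frac),
    sections_imaged = params$sections_imaged,
    sections_total = params$sections_total,
    stringsAsFactors = FALSE
  )
  list(counts = counts, starters = starters, truth = params)
}
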