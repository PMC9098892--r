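# Monosynaptic-tracing connectivity: starter interpolation, per-region
# connectivity ratios and group-level summary tables.

#' Interpolate a whole-brain starter-cell count
#'
#' Starter cells counted on a subset of sections are scaled to the full
#' section series: `starter_counted * sections_total / sections_imaged`.
#' Non-integer estimates are kept as real values.
#'
#' @param starter_counted starter cells counted on the imaged sections.
#' @param sections_imaged,sections_total imaged vs total section counts.
#' @return the whole-brain starter estimate (real-valued).
#' @export
interpolate_starters <- function(starter_counted, sections_imaged,
                                 sections_total) {
  abort_if(any(sections_imaged < 1), "sections_imaged must be >= 1")
  abort_if(any(sections_imaged > sections_total),
           "sections_imaged cannot exceed sections_total")
  abort_if(any(starter_counted < 0), "starter counts must be >= 0")
  starter_counted * sections_total / sections_imaged
}

#' Connectivity ratio of one region
#'
#' Presynaptic cell count in the region divided by the whole-brain starter
#' count. Brains with zero starters yield `NA` (they are excluded from group
#' summaries and reported, never coerced to infinity).
#'
#' @param region_count presynaptic cell count (vectorised).
#' @param starters_whole_brain whole-brain starter estimate.
#' @return connectivity ratio(s); `NA` where starters are zero.
#' @export
connectivity_ratio <- function(region_count, starters_whole_brain) {
  abort_if(any(region_count < 0), "presynaptic counts must be >= 0")
  abort_if(any(starters_whole_brain < 0), "starter counts must be >= 0")
  ifelse(starters_whole_brain > 0,
         region_count / starters_whole_brain, NA_real_)
}

#' Build a group-by-region connectivity table
#'
#' Joins per-brain presynaptic counts with starter counts, interpolates
#' starters, computes per-brain connectivity ratios and summarises each
#' (group, region, hemisphere) cell as mean +/- SEM with brain counts. When
#' comparison pairs are supplied, each (TBI group, matching control) pair is
#' compared per region with a two-tailed t-test through [standard_test()].
#'
#' @param counts data.frame (`brain_id`, `region`, `hemisphere`,
#'   `presyn_count`).
#' @param starters data.frame (`brain_id`, `group`, `starter_counted`,
#'   `sections_imaged`, `sections_total`).
#' @param comparisons optional list of `c(group, control_group)` pairs;
#'   set `NULL` to skip testing.
#' @return list with
#'   \describe{
#'     \item{ratios}{per (brain, region) table with `starters_interpolated`
#'       and `connectivity_ratio`.}
#'     \item{table}{per (group, region, hemisphere) mean/SEM/n summary.}
#'     \item{comparisons}{per-region test results for each requested pair
#'       (`NULL` when not requested).}
#'     \item{excluded_brains}{brains dropped for zero starters.}
#'   }
#' @export
build_connectivity_table <- function(counts, starters, comparisons = NULL) {
  req_c <- c("brain_id", "region", "hemisphere", "presyn_count")
  req_s <- c("brain_id", "group", "starter_counted", "sections_imaged",
             "sections_total")
  abort_if(!all(req_c %in% names(counts)), "counts must have columns %s",
           paste(req_c, collapse = ", "))
  abort_if(!all(req_s %in% names(starters)), "starters must have columns %s",
           paste(req_s, collapse = ", "))
  missing_b <- setdiff(counts$brain_id, starters$brain_id)
  abort_if(length(missing_b) > 0, "no starter record for brain(s): %s",
           paste(missing_b, collapse = ", "))

  starters$starters_interpolated <- interpolate_starters(
    starters$starter_counted, starters$sections_imaged, starters$sections_total)
  idx <- match(counts$brain_id, starters$brain_id)
  ratios <- counts
  ratios$group <- starters$group[idx]
  ratios$starters_interpolated <- starters$starters_interpolated[idx]
  ratios$connectivity_ratio <- connectivity_ratio(
    ratios$presyn_count, ratios$starters_interpolated)
  excluded <- unique(ratios$brain_id[ratios$starters_interpolated == 0])

  summary_tab <- aggregate_series(ratios, "connectivity_ratio",
                                  c("group", "hemisphere", "region"))

  comp_res <- NULL
  if (!is.null(comparisons)) {
    comp_res <- do.call(rbind, lapply(comparisons, function(pair) {
      g <- pair[[1L]]; ctrl <- pair[[2L]]
      per_region <- lapply(unique(ratios$region), function(r) {
        a <- ratios$connectivity_ratio[ratios$group == g & ratios$region == r]
        b <- ratios$connectivity_ratio[ratios$group == ctrl & ratios$region == r]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2L || length(b) < 2L) {
          return(data.frame(group = g, control = ctrl, region = r,
                            statistic = NA_real_, p_value = NA_real_,
                            stringsAsFactors = FALSE))
        }
        tt <- standard_test("t_two_sided", list(x = a, y = b))
        data.frame(group = g, control = ctrl, region = r,
                   statistic = tt$statistic, p_value = tt$p_value,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_region)
    }))
    rownames(comp_res) <- NULL
  }

  list(ratios = ratios, table = summary_tab, comparisons = comp_res,
       excluded_brains = excluded)
}
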