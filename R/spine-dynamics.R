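# Longitudinal spine-turnover statistics: transition classification,
# density, elimination/formation rates, morphology fractions and
# persistence indices, all computed from long-format presence tables.

validate_spine_tracks <- function(table, session_order = NULL) {
  required <- c("animal_id", "dendrite_id", "dendrite_length_um", "spine_id",
                "session", "present")
  missing <- setdiff(required, names(table))
  abort_if(length(missing) > 0, "spine table is missing columns: %s",
           paste(missing, collapse = ", "))
  abort_if(any(table$dendrite_length_um <= 0, na.rm = TRUE),
           "dendrite_length_um must be positive for every row")
  key <- paste(table$dendrite_id, table$spine_id, table$session, sep = "\r")
  dup <- anyDuplicated(key)
  abort_if(dup > 0, "duplicated (dendrite, spine, session) key at row %d", dup)
  if (!is.null(session_order)) {
    unknown <- setdiff(unique(table$session), session_order)
    abort_if(length(unknown) > 0, "unknown session label(s): %s",
             paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

# Dense presence matrix (spines x sessions) for one dendrite. Sessions before
# a spine's first row are treated as absent (0).
presence_matrix <- function(table, session_order) {
  spines <- unique(table$spine_id)
  m <- matrix(0L, nrow = length(spines), ncol = length(session_order),
              dimnames = list(spines, session_order))
  m[cbind(match(table$spine_id, spines), match(table$session, session_order))] <-
    as.integer(table$present)
  m
}

#' Classify spine transitions between consecutive imaging sessions
#'
#' For every dendrite and each consecutive session pair t-1 -> t, a spine
#' present at both sessions is stable, one present at t-1 but not t is
#' eliminated, and one present at t but not t-1 is formed. A spine that
#' reappears after elimination counts as a new formation (spine-id reuse
#' encodes same-location reappearance). Counts obey the conservation
#' identities `n_stable + n_eliminated = n_prev` and
#' `n_stable + n_formed = n_curr`.
#'
#' @param table long-format spine-tracking data.frame (see
#'   [simulate_spine_tracks()] for the schema).
#' @param session_order character vector giving the global session order;
#'   session labels are opaque and never sorted lexically.
#' @return data.frame with one row per (dendrite, session pair):
#'   `dendrite_id`, `session_from`, `session_to`, `n_prev`, `n_stable`,
#'   `n_eliminated`, `n_formed`, `n_curr`.
#' @export
classify_transitions <- function(table, session_order) {
  abort_if(length(session_order) < 2L,
           "at least 2 sessions are required to classify transitions")
  validate_spine_tracks(table, session_order)
  out <- lapply(split(table, table$dendrite_id), function(dt) {
    m <- presence_matrix(dt, session_order)
    k <- length(session_order)
    prev <- m[, 1:(k - 1), drop = FALSE]
    curr <- m[, 2:k, drop = FALSE]
    data.frame(
      dendrite_id = dt$dendrite_id[1L],
      session_from = session_order[1:(k - 1)],
      session_to = session_order[2:k],
      n_prev = colSums(prev),
      n_stable = colSums(prev == 1L & curr == 1L),
      n_eliminated = colSums(prev == 1L & curr == 0L),
      n_formed = colSums(prev == 0L & curr == 1L),
      n_curr = colSums(curr),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spine density per dendrite at a session
#'
#' Number of spines present at the session divided by the dendrite length
#' (spines per micrometre).
#'
#' @inheritParams classify_transitions
#' @param session session label to evaluate.
#' @return data.frame (`dendrite_id`, `n_present`, `dendrite_length_um`,
#'   `density_per_um`).
#' @export
spine_density <- function(table, session) {
  validate_spine_tracks(table)
  abort_if(!session %in% table$session, "unknown session label: %s", session)
  out <- lapply(split(table, table$dendrite_id), function(dt) {
    len <- dt$dendrite_length_um[1L]
    n_present <- sum(dt$present[dt$session == session] == 1L)
    data.frame(dendrite_id = dt$dendrite_id[1L], n_present = n_present,
               dendrite_length_um = len, density_per_um = n_present / len,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Elimination, formation and stable-fraction rates from transition counts
#'
#' Rates are the eliminated (or formed, or stable) spine count at a session
#' pair divided by the total spine count at the previous session, times 100.
#' Pairs with a zero previous count yield `NA` markers, never division
#' errors, and are excluded (with a count) by [aggregate_series()].
#'
#' @param counts output of [classify_transitions()].
#' @return the input with columns `elimination_rate_pct`,
#'   `formation_rate_pct`, `stable_fraction_pct` appended.
#' @export
turnover_rates <- function(counts) {
  required <- c("n_prev", "n_stable", "n_eliminated", "n_formed")
  abort_if(!all(required %in% names(counts)),
           "counts must come from classify_transitions()")
  denom <- ifelse(counts$n_prev > 0, counts$n_prev, NA_real_)
  counts$elimination_rate_pct <- 100 * counts$n_eliminated / denom
  counts$formation_rate_pct <- 100 * counts$n_formed / denom
  counts$stable_fraction_pct <- 100 * counts$n_stable / denom
  counts
}

#' Persistence indices of pre-existing and newly formed spines
#'
#' Every spine carries a binary presence code over the ordered sessions
#' (1 = present, 0 = eliminated). A spine present at every baseline session
#' is pre-existing; a spine absent at all baselines whose first presence is
#' after the last baseline is newly formed. Under the default
#' `denominator = "post_baseline"` convention, the index of a pre-existing
#' spine is the mean of its code over the post-baseline sessions, and that of
#' a newly formed spine the mean over sessions strictly after its birth
#' session (undefined when it is born at the final session). Under
#' `denominator = "all_sessions"` the index is the sum of the full code
#' divided by the total number of imaging time points, for both classes.
#'
#' Spines present at some but not all baseline sessions fit neither class;
#' they receive class `"ambiguous_baseline"` and an `NA` index.
#'
#' @inheritParams classify_transitions
#' @param baseline_sessions labels of the baseline sessions (must be a prefix
#'   of `session_order`).
#' @param denominator `"post_baseline"` (default) or `"all_sessions"`.
#' @return data.frame (`dendrite_id`, `spine_id`, `class`, `birth_session`,
#'   `persistence_index`).
#' @export
persistence_index <- function(table, session_order, baseline_sessions,
                              denominator = c("post_baseline", "all_sessions")) {
  denominator <- match.arg(denominator)
  validate_spine_tracks(table, session_order)
  abort_if(!all(baseline_sessions %in% session_order),
           "baseline_sessions must be a subset of session_order")
  base_idx <- match(baseline_sessions, session_order)
  abort_if(!identical(sort(base_idx), seq_along(base_idx)),
           "baseline_sessions must be the leading sessions of session_order")
  last_base <- max(base_idx)
  k <- length(session_order)

  out <- lapply(split(table, table$dendrite_id), function(dt) {
    m <- presence_matrix(dt, session_order)
    res <- lapply(rownames(m), function(s) {
      code <- m[s, ]
      pre_existing <- all(code[base_idx] == 1L)
      absent_baseline <- all(code[base_idx] == 0L)
      birth <- if (any(code == 1L)) which(code == 1L)[1L] else NA_integer_
      if (pre_existing) {
        cls <- "pre_existing"
        idx <- switch(denominator,
          post_baseline = mean(code[(last_base + 1):k]),
          all_sessions = sum(code) / k)
        birth_s <- session_order[1L]
      } else if (absent_baseline && !is.na(birth) && birth > last_base) {
        cls <- "newly_formed"
        idx <- switch(denominator,
          post_baseline = if (birth < k) mean(code[(birth + 1):k]) else NA_real_,
          all_sessions = sum(code) / k)
        birth_s <- session_order[birth]
      } else {
        cls <- "ambiguous_baseline"
        idx <- NA_real_
        birth_s <- if (is.na(birth)) NA_character_ else session_order[birth]
      }
      data.frame(dendrite_id = dt$dendrite_id[1L], spine_id = s, class = cls,
                 birth_session = birth_s, persistence_index = idx,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fractions of mushroom, thin and stubby spines
#'
#' Fractions of each morphology class among the spines present at a session,
#' per dendrite. Fractions sum to 1 whenever at least one spine is present;
#' a dendrite with no present spine yields `NA` fractions.
#'
#' @inheritParams spine_density
#' @param types morphology labels defining the fraction columns.
#' @return data.frame (`dendrite_id`, `n_present`, one `frac_<type>` column
#'   per type).
#' @export
morphology_fractions <- function(table, session,
                                 types = c("mushroom", "thin", "stubby")) {
  validate_spine_tracks(table)
  abort_if(!session %in% table$session, "unknown session label: %s", session)
  sub <- table[table$session == session & table$present == 1L, , drop = FALSE]
  missing_lab <- sub$spine_id[is.na(sub$morph_type)]
  abort_if(length(missing_lab) > 0,
           "missing morph_type for present spine(s): %s",
           paste(utils::head(missing_lab, 10L), collapse = ", "))
  unknown <- setdiff(unique(sub$morph_type), types)
  abort_if(length(unknown) > 0, "unknown morph_type label(s): %s",
           paste(unknown, collapse = ", "))
  out <- lapply(split(table, table$dendrite_id), function(dt) {
    labs <- dt$morph_type[dt$session == session & dt$present == 1L]
    n <- length(labs)
    fr <- if (n > 0) as.numeric(table(factor(labs, levels = types))) / n
          else rep(NA_real_, length(types))
    row <- data.frame(dendrite_id = dt$dendrite_id[1L], n_present = n,
                      stringsAsFactors = FALSE)
    row[paste0("frac_", types)] <- as.list(fr)
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate a per-dendrite series to mean +/- SEM
#'
#' Groups a long results table by the chosen unit columns and summarises one
#' value column as mean, SEM (`sd/sqrt(n)`), n and the number of `NA`
#' (undefined) values excluded.
#'
#' @param series data.frame of per-unit values.
#' @param value name of the numeric column to summarise.
#' @param by character vector of grouping columns (e.g. `"session_to"`, or
#'   `c("animal_id", "session_to")`).
#' @return data.frame with the grouping columns plus `mean`, `sem`, `n`,
#'   `n_excluded`.
#' @export
aggregate_series <- function(series, value, by) {
  abort_if(!value %in% names(series), "no column named '%s'", value)
  abort_if(!all(by %in% names(series)), "missing grouping column(s): %s",
           paste(setdiff(by, names(series)), collapse = ", "))
  groups <- interaction(series[by], drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(seq_len(nrow(series)), groups), function(idx) {
    cbind(series[idx[1L], by, drop = FALSE], mean_sem(series[[value]][idx]))
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}
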