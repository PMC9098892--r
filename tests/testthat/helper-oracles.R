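# Test helpers: fixture builders and independent brute-force oracles.

# Build a one-dendrite spine table from per-spine binary presence codes.
# codes: named list spine_id -> integer vector over sessions.
tracks_from_codes <- function(codes, sessions, length_um = 60,
                              morph = "mushroom") {
  rows <- lapply(names(codes), function(s) {
    code <- codes[[s]]
    stopifnot(length(code) == length(sessions))
    first <- which(code == 1L)[1L]
    if (is.na(first)) return(NULL)  # never-present spines have no rows
    keep <- first:length(sessions)
    data.frame(animal_id = "a01", dendrite_id = "d1",
               dendrite_length_um = length_um, spine_id = s,
               session = sessions[keep], present = code[keep],
               morph_type = ifelse(code[keep] == 1L, morph, NA_character_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Independent persistence oracle: explicit loops over one binary code.
# Returns list(class, index) for a code over k sessions with n_base leading
# baseline sessions, under the given denominator convention.
oracle_persistence <- function(code, n_base, denominator) {
  k <- length(code)
  all_base_present <- TRUE
  any_base_present <- FALSE
  for (i in 1:n_base) {
    if (code[i] == 1L) any_base_present <- TRUE else all_base_present <- FALSE
  }
  birth <- NA_integer_
  for (i in 1:k) if (code[i] == 1L) { birth <- i; break }
  if (all_base_present) {
    cls <- "pre_existing"
    if (denominator == "all_sessions") {
      idx <- sum(code) / k
    } else {
      post <- code[(n_base + 1):k]
      idx <- sum(post) / length(post)
    }
  } else if (!any_base_present && !is.na(birth) && birth > n_base) {
    cls <- "newly_formed"
    if (denominator == "all_sessions") {
      idx <- sum(code) / k
    } else if (birth < k) {
      after <- code[(birth + 1):k]
      idx <- sum(after) / length(after)
    } else {
      idx <- NA_real_
    }
  } else {
    cls <- "ambiguous_baseline"
    idx <- NA_real_
  }
  list(class = cls, index = idx)
}

# All binary codes of a given length, as rows of a matrix.
all_binary_codes <- function(len) {
  as.matrix(expand.grid(rep(list(0:1), len)))
}
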