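#!/usr/bin/env Rscript
# Functional analysis of the simulated calcium cohorts: per-neuron activity
# calls per session, fraction active with bootstrap CIs, high/low baseline
# split, and the two fate taxonomies, compared between callosal and
# non-callosal populations.
# Reads results/data/calcium_*.csv; writes results/calcium/*.csv.

suppressPackageStartupMessages(library(contraplast))

seed <- 20260903L
out <- "results/calcium"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
sessions <- c("baseline", "d10", "d42")
pops <- c("callosal", "non_callosal")

activity <- NULL
for (pop in pops) {
  for (sess in sessions) {
    traces <- read_traces(sprintf("results/data/calcium_%s_%s.csv", pop, sess))
    res <- analyze_traces(traces, frame_rate_hz = 30)
    activity <- rbind(activity,
                      cbind(population = pop, session = sess, res))
  }
}
write.csv(activity, file.path(out, "activity_per_neuron.csv"), row.names = FALSE)

frac <- NULL
for (pop in pops) {
  for (sess in sessions) {
    a <- activity$active[activity$population == pop & activity$session == sess]
    b <- bootstrap_fraction_ci(a, n_iterations = 10000,
                               seed = child_seed(seed, 1))
    frac <- rbind(frac, data.frame(population = pop, session = sess,
                                   n = length(a), fraction_active = b$estimate,
                                   ci_low = b$ci_low, ci_high = b$ci_high))
    message(sprintf("%-12s %-8s fraction active %.3f (95%% CI %.3f-%.3f, n=%d)",
                    pop, sess, b$estimate, b$ci_low, b$ci_high, length(a)))
  }
}
write.csv(frac, file.path(out, "fraction_active.csv"), row.names = FALSE)

# fate taxonomies per population; difference tested by bootstrap
fates <- NULL
for (pop in pops) {
  sub <- activity[activity$population == pop, ]
  wide <- reshape(sub[c("neuron_id", "session", "active")],
                  idvar = "neuron_id", timevar = "session",
                  direction = "wide")
  f <- classify_fate(wide$active.baseline, wide$active.d10, wide$active.d42,
                     wide$neuron_id)
  fates <- rbind(fates, cbind(population = pop, f))
}
write.csv(fates, file.path(out, "fate_taxonomy.csv"), row.names = FALSE)

silent_mid <- lapply(pops, function(pop) {
  f <- fates[fates$population == pop & fates$baseline, ]
  f$fate_from_baseline == "silent_at_mid"
})
bt <- bootstrap_difference_test(silent_mid[[1]], silent_mid[[2]],
                                n_iterations = 10000,
                                seed = child_seed(seed, 2))
message(sprintf(
  "silent-at-mid fraction, callosal %.3f vs non-callosal %.3f: bootstrap p = %.4g",
  mean(silent_mid[[1]]), mean(silent_mid[[2]]), bt$p_value))

# baseline high/low level vs remaining active at the late session
base <- activity[activity$session == "baseline", ]
late <- activity[activity$session == "d42", ]
lv <- merge(base[c("population", "neuron_id", "level")],
            late[c("population", "neuron_id", "active")],
            by = c("population", "neuron_id"))
split_tab <- do.call(rbind, lapply(pops, function(pop) {
  do.call(rbind, lapply(c("high", "low"), function(level) {
    a <- lv$active[lv$population == pop & lv$level == level]
    if (length(a) == 0) return(NULL)
    b <- bootstrap_fraction_ci(a, n_iterations = 10000,
                               seed = child_seed(seed, 3))
    data.frame(population = pop, baseline_level = level, n = length(a),
               fraction_active_late = b$estimate,
               ci_low = b$ci_low, ci_high = b$ci_high)
  }))
}))
write.csv(split_tab, file.path(out, "high_low_split.csv"), row.names = FALSE)
message("high/low baseline split written; see results/calcium/high_low_split.csv")
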