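# Spine-turnover statistics against hand counts and brute-force oracles.

sessions4 <- c("B1", "B2", "3d", "6d")

test_that("transition classification reproduces hand counts", {
  # 50 spines at t-1; 45 stay, 5 eliminated, 3 new at t
  codes <- c(
    setNames(lapply(1:45, function(i) c(1L, 1L)), sprintf("stay%02d", 1:45)),
    setNames(lapply(1:5, function(i) c(1L, 0L)), sprintf("gone%02d", 1:5)),
    setNames(lapply(1:3, function(i) c(0L, 1L)), sprintf("new%02d", 1:3)))
  tab <- tracks_from_codes(codes, c("t1", "t2"))
  tr <- classify_transitions(tab, c("t1", "t2"))
  expect_equal(tr$n_prev, 50)
  expect_equal(tr$n_stable, 45)
  expect_equal(tr$n_eliminated, 5)
  expect_equal(tr$n_formed, 3)
  expect_equal(tr$n_curr, 48)
})

test_that("a 1,0,1 code is one elimination then one (re)formation", {
  tab <- tracks_from_codes(list(s1 = c(1L, 0L, 1L)), c("t1", "t2", "t3"))
  tr <- classify_transitions(tab, c("t1", "t2", "t3"))
  expect_equal(tr$n_eliminated, c(1, 0))
  expect_equal(tr$n_formed, c(0, 1))
})

test_that("all-stable tables have zero turnover", {
  codes <- setNames(lapply(1:10, function(i) c(1L, 1L)), sprintf("s%02d", 1:10))
  tr <- classify_transitions(tracks_from_codes(codes, c("t1", "t2")),
                             c("t1", "t2"))
  expect_equal(tr$n_eliminated + tr$n_formed, 0)
  expect_equal(tr$n_stable, tr$n_prev)
})

test_that("transition classification enforces its contract", {
  tab <- tracks_from_codes(list(s1 = 1L), "t1")
  expect_error(classify_transitions(tab, "t1"), "2 sessions")
  tab2 <- tracks_from_codes(list(s1 = c(1L, 1L)), c("t1", "t2"))
  tab2$session[2] <- "zz"
  expect_error(classify_transitions(tab2, c("t1", "t2")), "zz")
  dup <- rbind(tab2[1, ], tab2[1, ])
  expect_error(classify_transitions(dup, c("t1", "t2")), "duplicated")
})

test_that("density is spines present over dendrite length", {
  codes <- setNames(lapply(1:24, function(i) c(1L, 0L)), sprintf("s%02d", 1:24))
  tab <- tracks_from_codes(codes, c("t1", "t2"), length_um = 60)
  expect_equal(spine_density(tab, "t1")$density_per_um, 0.4)
  expect_equal(spine_density(tab, "t2")$density_per_um, 0)
  # scale invariance: doubling spines and length leaves density unchanged
  codes2 <- c(codes, setNames(lapply(1:24, function(i) c(1L, 0L)),
                              sprintf("x%02d", 1:24)))
  tab2 <- tracks_from_codes(codes2, c("t1", "t2"), length_um = 120)
  expect_equal(spine_density(tab2, "t1")$density_per_um, 0.4)
  tab$dendrite_length_um <- 0
  expect_error(spine_density(tab, "t1"), "positive")
})

test_that("turnover rates are percentages of the previous total", {
  counts <- data.frame(dendrite_id = "d1", session_from = c("a", "b", "c"),
                       session_to = c("b", "c", "d"),
                       n_prev = c(50, 10, 0), n_stable = c(45, 10, 0),
                       n_eliminated = c(5, 0, 0), n_formed = c(3, 0, 2),
                       n_curr = c(48, 10, 2))
  r <- turnover_rates(counts)
  expect_equal(r$elimination_rate_pct, c(10, 0, NA_real_))
  expect_equal(r$formation_rate_pct, c(6, 0, NA_real_))
  expect_equal(r$stable_fraction_pct, c(90, 100, NA_real_))
  agg <- aggregate_series(r, "elimination_rate_pct", "dendrite_id")
  expect_equal(agg$n, 2)
  expect_equal(agg$n_excluded, 1)
})

test_that("conservation identities hold on simulated tables", {
  for (seed in 1:5) {
    p <- spine_sim_params(n_dendrites = 10, spines_per_dendrite_mean = 30,
                          session_times = sessions4,
                          elimination_prob = 0.2, formation_rate = 0.15,
                          seed = seed)
    tr <- classify_transitions(simulate_spine_tracks(p)$tracks, sessions4)
    expect_identical(tr$n_stable + tr$n_eliminated, tr$n_prev)
    expect_identical(tr$n_stable + tr$n_formed, tr$n_curr)
    # density recursion: N_t = N_{t-1} - eliminated + formed
    expect_identical(tr$n_curr, tr$n_prev - tr$n_eliminated + tr$n_formed)
  }
})

test_that("persistence index matches hand-computed examples", {
  sess <- c("B1", "B2", "p1", "p2", "p3", "p4")
  tab <- tracks_from_codes(
    list(always = c(1L, 1L, 1L, 1L, 1L, 1L),
         alt = c(1L, 1L, 1L, 0L, 1L, 0L),      # post-baseline 1,0,1,0
         born3 = c(0L, 0L, 1L, 1L, 1L, 1L),     # newly formed, persists
         born3b = c(0L, 0L, 1L, 1L, 0L, 0L),    # present at 1 of 3 after birth
         lastborn = c(0L, 0L, 0L, 0L, 0L, 1L)), # born at final session
    sess)
  pi <- persistence_index(tab, sess, c("B1", "B2"))
  idx <- setNames(pi$persistence_index, pi$spine_id)
  cls <- setNames(pi$class, pi$spine_id)
  expect_equal(idx[["always"]], 1)
  expect_equal(idx[["alt"]], 0.5)
  expect_equal(cls[["born3"]], "newly_formed")
  expect_equal(idx[["born3"]], 1)
  expect_equal(idx[["born3b"]], 1 / 3)
  expect_true(is.na(idx[["lastborn"]]))  # zero-length denominator
})

test_that("persistence index matches brute force over all codes up to length 6", {
  for (k in 3:6) {
    sessions <- c("B1", "B2", paste0("p", seq_len(k - 2)))
    codes <- all_binary_codes(k)
    for (denom in c("post_baseline", "all_sessions")) {
      for (i in seq_len(nrow(codes))) {
        code <- as.integer(codes[i, ])
        if (all(code == 0L)) next  # never-present spines have no table rows
        tab <- tracks_from_codes(list(s = code), sessions)
        got <- persistence_index(tab, sessions, c("B1", "B2"), denom)
        want <- oracle_persistence(code, 2L, denom)
        expect_equal(got$class, want$class,
                     info = sprintf("k=%d code=%s denom=%s", k,
                                    paste(code, collapse = ""), denom))
        expect_equal(got$persistence_index, want$index,
                     info = sprintf("k=%d code=%s denom=%s", k,
                                    paste(code, collapse = ""), denom))
      }
    }
  }
})

test_that("morphology fractions sum to one and match hand arithmetic", {
  codes <- setNames(lapply(1:10, function(i) c(1L, 0L)), sprintf("s%02d", 1:10))
  tab <- tracks_from_codes(codes, c("t1", "t2"))
  tab$morph_type[tab$session == "t1"] <-
    rep(c("mushroom", "thin", "stubby"), c(6, 3, 1))
  fr <- morphology_fractions(tab, "t1")
  expect_equal(fr$frac_mushroom, 0.6)
  expect_equal(fr$frac_thin, 0.3)
  expect_equal(fr$frac_stubby, 0.1)
  expect_equal(fr$frac_mushroom + fr$frac_thin + fr$frac_stubby, 1,
               tolerance = 1e-12)
  # no spines present -> undefined marker
  fr2 <- morphology_fractions(tab, "t2")
  expect_true(all(is.na(c(fr2$frac_mushroom, fr2$frac_thin, fr2$frac_stubby))))
  # missing labels are an error naming the spines
  tab$morph_type[tab$session == "t1"][1] <- NA
  expect_error(morphology_fractions(tab, "t1"), "s01")
})

test_that("estimators are invariant to row order and spine relabeling", {
  p <- spine_sim_params(n_dendrites = 6, spines_per_dendrite_mean = 25,
                        session_times = sessions4, seed = 31)
  tab <- simulate_spine_tracks(p)$tracks
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(classify_transitions(shuf, sessions4),
               classify_transitions(tab, sessions4))
  relab <- tab
  relab$spine_id <- paste0("zz_", relab$spine_id)
  tr_a <- classify_transitions(tab, sessions4)
  tr_b <- classify_transitions(relab, sessions4)
  expect_equal(tr_a[setdiff(names(tr_a), "spine_id")],
               tr_b[setdiff(names(tr_b), "spine_id")])
})

test_that("aggregate_series matches the closed-form SEM and ignores order", {
  s <- data.frame(g = "a", v = c(1, 2, 3))
  agg <- aggregate_series(s, "v", "g")
  expect_equal(agg$mean, 2)
  expect_equal(agg$sem, stats::sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(round(agg$sem, 4), 0.5774)
  expect_equal(aggregate_series(s[c(3, 1, 2), ], "v", "g"), agg)
  one <- aggregate_series(data.frame(g = "a", v = 5), "v", "g")
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sem))
})
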