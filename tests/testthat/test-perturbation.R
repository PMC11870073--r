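port_table <- function(onsets) {
  data.frame(trigger_lick_idx = NA_integer_, move_onset_s = onsets,
             direction = "rightward", displacement_mm = 3,
             travel_s = 0.05, return_s = onsets + 0.75)
}

test_that("every trial with enough following licks yields indices 0 to 3", {
  lt <- comb_licks(n_bouts = 10, size = 10, gap = 3)
  onsets <- lt$detect_times[seq(2, 92, by = 10)] + 0.04
  tl <- index_trial_licks(port_table(onsets), lt)
  right <- tl$indexed[tl$indexed$direction == "rightward", ]
  for (e in unique(right$event_id)) {
    expect_equal(sort(right$lick_index[right$event_id == e]), 0:3)
  }
})

test_that("a movement at the end of a bout is excluded from follow-up analyses", {
  lt <- comb_licks(n_bouts = 4, size = 5, gap = 5)
  last <- lt$detect_times[5]            # last lick of the first bout
  tl <- index_trial_licks(port_table(last + 0.04), lt)
  right <- tl$indexed[tl$indexed$direction == "rightward", ]
  # next bout starts > 0.75 s later: rightward window has no licks
  expect_equal(tl$n_excluded, 1L)
  expect_false(any(right$lick_index > 0))
})

test_that("trial lick indexing matches a brute-force scan", {
  set.seed(91)
  for (i in 1:80) {
    lk <- sort(runif(sample(20:80, 1), 0, 60))
    ev <- sort(runif(sample(2:6, 1), 5, 55))
    trials <- data.frame(trigger_lick_idx = NA, move_onset_s = ev,
                         direction = "rightward", displacement_mm = 3,
                         return_s = ev + 0.75)
    all_events <- sort(c(ev, ev + 0.75))
    want <- oracle_index_licks(all_events, lk)
    lt <- lick_train(lk, session_duration = 61)
    got <- index_trial_licks(trials, lt)$indexed
    expect_equal(got$lick, want$lick)
    expect_equal(got$lick_index, want$lick_index)
  }
})

test_that("baseline licks keep clear of every trial span", {
  lt <- comb_licks(n_bouts = 12, size = 10, gap = 2)
  onsets <- lt$detect_times[c(15, 55, 95)] + 0.04
  tl <- index_trial_licks(port_table(onsets), lt)
  t <- lt$detect_times[tl$baseline_licks]
  for (o in onsets) expect_false(any(t >= o & t < o + 1.8))
})

test_that("normalization is relative to pre-movement licks and idempotent", {
  lt <- comb_licks(n_bouts = 6, size = 10, gap = 3)
  n <- n_licks(lt)
  lt$endpoint_x <- rep(0, n)
  lt$endpoint_y <- rep(4, n)
  onsets <- lt$detect_times[seq(4, 54, by = 10)] + 0.04
  # displace every lick after each onset by +3 until the return
  for (o in onsets) {
    k <- which(lt$detect_times > o & lt$detect_times <= o + 0.75)
    lt$endpoint_x[k] <- 3
  }
  tl <- normalize_trial_coordinates(index_trial_licks(port_table(onsets), lt), lt)
  right <- tl$indexed[tl$indexed$direction == "rightward", ]
  expect_equal(right$norm_x[right$lick_index == 0], rep(0, 6))
  expect_equal(right$norm_x[right$lick_index > 0],
               rep(3, sum(right$lick_index > 0)))
  # the endpoints were already expressed relative to the pre-movement
  # position, so normalization reproduced them unchanged
  expect_equal(right$norm_x, right$x)
  summ <- adaptation_summary(tl)
  expect_equal(summ$mean_x[summ$direction == "rightward" & summ$lick_index == 2], 3)
})

test_that("a cell with no complex spikes is never movement-responsive", {
  lt <- comb_licks(n_bouts = 30, size = 8, gap = 2)
  bouts <- segment_bouts(lt)
  onsets <- lt$detect_times[seq(2, 234, by = 8)] + 0.04
  cell <- cell_recording("e", ss_times = seq(0.1, 90, by = 0.02),
                         cs_times = numeric(0))
  res <- cs_move_response(cell, port_table(onsets), bouts,
                          session_duration = lt$session_duration)
  expect_false(res$responsive)
})

test_that("movement-locked CS bumps give positive direction selectivity", {
  pos <- 0
  for (seed in 1:4) {
    gen <- generate_session(
      behaviour_spec(), list(a = cell_spec(ss_base_rate = 5,
                                           cs_move_gain_right = 5)),
      duration = 350, seed = seed, n_port_trials = 30)
    sess <- gen$session
    bouts <- segment_bouts(sess$licks)
    sel <- cs_move_selectivity(sess$cells$a, sess$port_trials, bouts,
                               session_duration = 350)
    pos <- pos + (sel$selectivity > 0)
    expect_true(sel$rightward$responsive)
  }
  expect_gte(pos, 3)
})

test_that("shared spike trains give exactly zero adaptation peak differences", {
  gen <- generate_session(behaviour_spec(), list(a = cell_spec()),
                          duration = 300, seed = 6, n_port_trials = 20)
  sess <- gen$session
  tl <- index_trial_licks(sess$port_trials, sess$licks)
  # force both directions onto the same lick sets: peaks must coincide
  ind <- tl$indexed
  ind_r <- ind[ind$direction == "rightward", ]
  ind_c <- ind_r; ind_c$direction <- "centreward"
  tl$indexed <- rbind(ind_r, ind_c)
  pk <- ss_adaptation_peaks(sess$cells$a, tl, sess$licks)
  for (k in unique(pk$lick_index)) {
    expect_equal(pk$peak_z[pk$direction == "rightward" & pk$lick_index == k],
                 pk$peak_z[pk$direction == "centreward" & pk$lick_index == k])
  }
})

test_that("optogenetic bend and shortening are recovered from the session", {
  gen <- generate_session(
    behaviour_spec(), list(), duration = 500, seed = 8,
    opto_plan = list(n_trials = 60,
                     arms = data.frame(onset_offset_s = 0.010,
                                       duration_s = 0.160,
                                       fibre = c("right_medial", "left_medial"))))
  sess <- gen$session
  stim_trig <- sess$opto_trials$trigger_lick_idx
  affected <- gen$truth$opto_affected
  # controls: licks whose following three licks are all unstimulated
  controls <- setdiff(which(sess$licks$detect_times <
                              sess$licks$session_duration - 1),
                      c(stim_trig, affected, affected - 1, affected - 2,
                        affected - 3))
  eff <- opto_effect(sess$licks, sess$opto_trials, controls)
  r1 <- eff[eff$fibre == "right_medial" & eff$lick_index == 1, ]
  l1 <- eff[eff$fibre == "left_medial" & eff$lick_index == 1, ]
  expect_gt(r1$dx, 0.2)
  expect_lt(l1$dx, -0.2)
  expect_lt(r1$dy, -0.1)
})
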