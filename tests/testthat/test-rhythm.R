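test_that("phase anchors sit at 0, pi and 2*pi by construction", {
  lt <- comb_licks(n_bouts = 3, size = 6)
  pm <- build_phase_map(lt)
  m <- max_protrusion(lt)
  ph <- phase_at(pm, m)
  expect_equal(ph$phase[!is.na(ph$phase)],
               rep(pi, sum(!is.na(ph$phase))))
  # the midpoint between two maximal protrusions is the cycle boundary
  mid <- (m[1] + m[2]) / 2
  expect_true(phase_at(pm, mid)$phase %in% c(0, 2 * pi))
})

test_that("maximal protrusion maps to pi whatever the lick jitter", {
  set.seed(51)
  for (i in 1:20) {
    det <- cumsum(runif(15, 0.12, 0.3))
    lt <- lick_train(det, session_duration = max(det) + 1,
                     max_protrusion_times = det + 0.016)
    pm <- build_phase_map(lt, max_gap = 1)
    ph <- phase_at(pm, max_protrusion(lt))$phase
    expect_equal(ph, rep(pi, length(ph)))
  }
})

test_that("single-lick bouts carry no phase", {
  lt <- lick_train(c(1, 5, 5.15, 5.30), session_duration = 10,
                   max_protrusion_times = c(1, 5, 5.15, 5.30) + 0.016)
  pm <- build_phase_map(lt)
  expect_true(is.na(phase_at(pm, 1.0)$phase))
  expect_false(is.na(phase_at(pm, 5.15 + 0.016)$phase))
})

test_that("a spike comb at maximal protrusion is fully coherent at phase pi", {
  lt <- comb_licks(n_bouts = 40, size = 10)
  pm <- build_phase_map(lt)
  res <- lick_coherence(max_protrusion(lt), pm, min_spikes = 50)
  expect_gt(res$msc, 0.95)
  expect_lt(abs(res$phase - pi), 0.1)
  expect_true(res$coherent)
})

test_that("coherence is invariant to a whole-cycle shift of the spikes", {
  lt <- comb_licks(n_bouts = 40, size = 10, T = 0.16)
  pm <- build_phase_map(lt)
  r0 <- lick_coherence(max_protrusion(lt), pm, min_spikes = 50)
  r1 <- lick_coherence(max_protrusion(lt) + 0.16, pm, min_spikes = 50)
  expect_lt(abs(r0$msc - r1$msc), 0.02)
  expect_lt(abs(r0$phase - r1$phase), 0.1)
})

test_that("phase and coherence recover the generator's locking", {
  ok_phase <- 0; ok_msc <- 0; null_high <- 0
  for (seed in 1:5) {
    lt <- generate_licks(behaviour_spec(), duration = 300, seed = seed)
    pm <- build_phase_map(lt)
    pref <- c(0, pi / 2, pi, 3 * pi / 2, 1)[seed]
    cell <- generate_cell(cell_spec(ss_kappa = 4, ss_phase_pref = pref),
                          lt, seed = seed + 60)
    res <- lick_coherence(cell$ss_times, pm)
    d <- abs(res$phase - pref) %% (2 * pi)
    ok_phase <- ok_phase + (min(d, 2 * pi - d) < 0.2)
    ok_msc <- ok_msc + (res$msc > 0.5)
    null_cell <- generate_cell(cell_spec(ss_kappa = 0), lt, seed = seed + 90)
    null_high <- null_high + (lick_coherence(null_cell$ss_times, pm)$msc > 0.5)
  }
  expect_equal(ok_phase, 5)
  expect_equal(ok_msc, 5)
  expect_lte(null_high, 1)
})

test_that("undersampled spike trains are flagged, not classified", {
  lt <- comb_licks(n_bouts = 20, size = 8)
  pm <- build_phase_map(lt)
  res <- lick_coherence(max_protrusion(lt)[1:30], pm, min_spikes = 100)
  expect_true(res$low_power)
  expect_true(is.na(res$coherent))
})

test_that("a 6 Hz in-bout comb peaks at 6 Hz only inside bouts", {
  lt <- comb_licks(n_bouts = 40, size = 12, T = 1 / 6, gap = 3)
  bouts <- segment_bouts(lt)
  ep <- bout_epochs(bouts, lt$session_duration)
  # spikes: a 6 Hz comb inside bouts, homogeneous 30 Hz outside
  in_spk <- lt$detect_times + 0.02
  set.seed(7)
  out_spk <- sort(unlist(apply(ep$out_bout, 1, function(e)
    runif(round(30 * (e[2] - e[1])), e[1], e[2]))))
  res <- autocorr_power(sort(c(in_spk, out_spk)), lt, bouts)
  expect_equal(res$preferred_lick_freq, 6, tolerance = 0.15)
  in_peak_f <- res$freq_grid[res$freq_grid > 0.5 & res$freq_grid < 25]
  pin <- res$power_in_bout[res$freq_grid > 0.5 & res$freq_grid < 25]
  expect_equal(in_peak_f[which.max(pin)], 6, tolerance = 0.15)
  expect_gt(res$power_at_pref_in, res$power_at_pref_out)
})

test_that("in-bout rhythmic power exceeds out-of-bout power for locked cells", {
  wins <- 0
  for (seed in 1:5) {
    lt <- generate_licks(behaviour_spec(), duration = 300, seed = seed)
    cell <- generate_cell(cell_spec(ss_kappa = 4), lt, seed = seed + 70)
    res <- autocorr_power(cell$ss_times, lt)
    wins <- wins + (res$power_at_pref_in > res$power_at_pref_out)
  }
  expect_gte(wins, 4)
})

test_that("grid reduction equals brute-force 2x2 neighbourhood means", {
  # constant input stays constant
  full <- expand.grid(r = 1:8, c = 1:4)
  out <- grid_summary(rep(3.5, 32), full$r, full$c)
  expect_equal(out, matrix(3.5, 7, 3))

  # a single populated electrode feeds only its one neighbourhood
  out1 <- grid_summary(2.2, 1, 1)
  expect_equal(out1[1, 1], 2.2)
  expect_equal(sum(!is.na(out1)), 1)

  set.seed(61)
  for (i in 1:50) {
    n <- sample(1:32, 1)
    pos <- full[sample(32, n), ]
    v <- rnorm(n)
    expect_equal(grid_summary(v, pos$r, pos$c),
                 oracle_grid_summary(v, pos$r, pos$c))
  }
  expect_error(grid_summary(1, 9, 1), "out of")
})
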