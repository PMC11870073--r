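test_that("degenerate interval CV gives a perfectly regular comb", {
  lt <- generate_licks(behaviour_spec(ili_cv = 0), duration = 60, seed = 1)
  bouts <- segment_bouts(lt)
  for (b in seq_len(nrow(bouts))) {
    idx <- bouts$first_lick_index[b]:bouts$last_lick_index[b]
    if (length(idx) > 1) {
      expect_equal(diff(lt$detect_times[idx]), rep(0.16, length(idx) - 1),
                   tolerance = 1e-6 / 0.16)
    }
  }
})

test_that("segment_bouts recovers the generated bout partition exactly", {
  for (seed in c(2, 7, 19)) {
    lt <- generate_licks(behaviour_spec(), duration = 300, seed = seed)
    bouts <- segment_bouts(lt)
    got <- rep(seq_len(nrow(bouts)), bouts$n_licks)
    expect_identical(got, as.integer(attr(lt, "bout_id")))
  }
})

test_that("intra-bout intervals have the configured mean", {
  lt <- generate_licks(behaviour_spec(), duration = 5000, seed = 5)
  bouts <- segment_bouts(lt)
  ili <- unlist(lapply(seq_len(nrow(bouts)), function(b) {
    idx <- bouts$first_lick_index[b]:bouts$last_lick_index[b]
    diff(lt$detect_times[idx])
  }))
  expect_gt(length(ili), 1e4)
  se <- sd(ili) / sqrt(length(ili))
  expect_lt(abs(mean(ili) - 0.16), 2 * se + 1e-9)
})

test_that("an unlocked cell without complex spikes is homogeneous Poisson", {
  lt <- generate_licks(behaviour_spec(), duration = 200, seed = 3)
  cell <- generate_cell(cell_spec(ss_kappa = 0, cs_base_rate = 0,
                                  ss_base_rate = 50), lt, seed = 4)
  isi <- diff(cell$ss_times)
  # the RNG's ~2^-32 time granularity produces tied ISIs; the KS statistic
  # is unaffected at this sample size
  p <- suppressWarnings(
    stats::ks.test(isi, "pexp", rate = 1 / mean(isi))$p.value)
  expect_gt(p, 0.01)
  # empirical rate within 3 SE of the specified rate
  n <- length(cell$ss_times)
  expect_lt(abs(n / 200 - 50), 3 * sqrt(n) / 200)
})

test_that("complex-spike rate matches its specification", {
  lt <- generate_licks(behaviour_spec(), duration = 600, seed = 8)
  cell <- generate_cell(cell_spec(cs_base_rate = 1.2), lt, seed = 9)
  n <- length(cell$cs_times)
  expect_lt(abs(n / 600 - 1.2), 3 * sqrt(n) / 600)
})

test_that("phase-locked spikes concentrate at the preferred phase", {
  lt <- generate_licks(behaviour_spec(), duration = 300, seed = 6)
  cell <- generate_cell(cell_spec(ss_kappa = 4, ss_phase_pref = pi), lt,
                        seed = 7)
  ph <- phase_at(build_phase_map(lt), cell$ss_times)$phase
  ph <- ph[!is.na(ph)]
  expect_gt(length(ph), 5000)
  circ_mean <- Arg(mean(exp(1i * ph))) %% (2 * pi)
  expect_lt(abs(circ_mean - pi), 0.1)
})

test_that("the generator always honours the post-CS pause", {
  for (seed in 1:5) {
    lt <- generate_licks(behaviour_spec(), duration = 120, seed = seed)
    cell <- generate_cell(cell_spec(cs_base_rate = 2), lt, seed = seed + 100)
    expect_true(validate_cell(cell, n_trials = n_licks(lt))$pause_ok)
  }
})

test_that("sessions are reproducible and behaviour is cell-invariant", {
  spec2 <- list(a = cell_spec(), b = cell_spec(ss_kappa = 0))
  g1 <- generate_session(behaviour_spec(), spec2, duration = 90, seed = 12)
  g2 <- generate_session(behaviour_spec(), spec2, duration = 90, seed = 12)
  expect_identical(g1$session$licks, g2$session$licks)
  expect_identical(g1$session$cells$a$ss_times, g2$session$cells$a$ss_times)
  # adding a third cell must not perturb behaviour or earlier cells
  g3 <- generate_session(behaviour_spec(), c(spec2, list(c = cell_spec())),
                         duration = 90, seed = 12)
  expect_identical(g3$session$licks$detect_times,
                   g1$session$licks$detect_times)
  expect_identical(g3$session$cells$a$ss_times, g1$session$cells$a$ss_times)
})

test_that("port trial scheduling respects request, refractoriness and supply", {
  gen <- generate_session(behaviour_spec(), list(), duration = 300, seed = 13,
                          n_port_trials = 25)
  pt <- gen$session$port_trials
  expect_equal(nrow(pt), 25)
  # once triggered, the port is busy for onset + hold + refractory
  expect_true(all(diff(pt$move_onset_s) >= 1.5))
  expect_error(
    generate_session(behaviour_spec(), list(), duration = 30, seed = 13,
                     n_port_trials = 500),
    "over-subscribed")
})

test_that("trial-free sessions carry empty trial tables", {
  gen <- generate_session(behaviour_spec(), list(), duration = 60, seed = 14)
  expect_null(gen$session$port_trials)
  expect_null(gen$session$opto_trials)
})
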