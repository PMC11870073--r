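# a PSTH object with prescribed per-bin rates, for contract tests
psth_from_rates <- function(rates, bin = 0.010, t0 = -0.1, n_align = 100) {
  structure(list(edges = t0 + bin * (0:length(rates)),
                 counts = rates * n_align * bin, rate = rates, z = NULL,
                 n_align = n_align, bin = bin, baseline_window = NULL,
                 zero_sd = FALSE), class = "psth")
}

test_that("PSTH counting pools events over alignments", {
  align <- c(1, 2, 3, 4)
  p <- compute_psth(align, align, window = c(-0.05, 0.05))
  expect_equal(sum(p$counts), 4)
  # all mass in the bin whose left edge is 0, at 1/bin per alignment
  expect_equal(p$rate[p$edges[-length(p$edges)] == 0], 100)
  expect_equal(sum(p$rate), 100)

  p0 <- compute_psth(numeric(0), align, window = c(-0.05, 0.05))
  expect_equal(p0$counts, rep(0, 10))
})

test_that("PSTH counts match the brute-force per-alignment histogram", {
  set.seed(21)
  for (i in 1:60) {
    ev <- sort(runif(sample(10:120, 1), 0, 20))
    al <- sort(runif(sample(3:12, 1), 1, 19))
    dur <- if (i %% 2) 20 else NULL
    p <- compute_psth(ev, al, window = c(-0.3, 0.3), bin = 0.05,
                      session_duration = dur)
    expect_equal(p$counts,
                 oracle_psth_counts(ev, al, c(-0.3, 0.3), 0.05, dur))
  }
})

test_that("alignments whose window crosses the session edge are dropped", {
  p <- compute_psth(c(0.5, 5), c(0.5, 5), window = c(-1, 1),
                    session_duration = 10)
  expect_equal(p$n_align, 1)
  expect_equal(sum(p$counts), 1)
})

test_that("Z-scoring follows the definition and flags zero-SD baselines", {
  # baseline mean 10 Hz, SD 2 Hz; a 16 Hz bin scores Z = 3
  rates <- c(8, 12, 8, 12, 8, 12, 16)
  p <- zscore_psth(psth_from_rates(rates), baseline_window = c(-0.1, -0.04))
  expect_equal(p$baseline_mean, 10)
  expect_equal(tail(p$z, 1), (16 - 10) / sd(c(8, 12, 8, 12, 8, 12)))

  flat <- zscore_psth(psth_from_rates(rep(7, 10)),
                      baseline_window = c(-0.1, -0.05))
  expect_true(flat$zero_sd)
  expect_true(all(is.na(flat$z)))
})

test_that("Z-scores are invariant to affine rescaling of the rates", {
  rates <- c(5, 9, 6, 10, 7, 30, 4)
  p1 <- zscore_psth(psth_from_rates(rates), c(-0.1, -0.05))
  p2 <- zscore_psth(psth_from_rates(3 * rates + 2), c(-0.1, -0.05))
  expect_equal(p1$z, p2$z)
})

test_that("modulation depth is the max-min excursion in the window", {
  p <- psth_from_rates(c(10, 10, 30, 10), t0 = -0.02)
  expect_equal(modulation_depth(p, c(-0.02, 0.02))$depth, 20)
  flat <- psth_from_rates(rep(10, 20))
  res <- modulation_depth(flat, c(-0.1, 0.1))
  expect_equal(res$depth, 0)
  expect_false(res$significant)
})

test_that("false-positive rate of |Z|>3 bins is below 1% for Poisson cells", {
  set.seed(31)
  n_extreme <- 0; n_bins <- 0
  for (i in 1:25) {
    al <- sort(runif(300, 2, 598))
    ev <- sort(runif(30 * 600, 0, 600))  # 30 Hz homogeneous
    p <- compute_psth(ev, al, window = c(-1, 0.5), session_duration = 600)
    p <- zscore_psth(p, c(-1, -0.25))
    n_extreme <- n_extreme + sum(abs(p$z) > 3, na.rm = TRUE)
    n_bins <- n_bins + sum(!is.na(p$z))
  }
  expect_lt(n_extreme / n_bins, 0.01)
})

test_that("bout-transition responses recover the generator's CS bumps", {
  hits_start <- hits_end <- 0
  for (seed in 1:6) {
    lt <- generate_licks(behaviour_spec(), duration = 300, seed = seed)
    bouts <- segment_bouts(lt)
    cell <- generate_cell(cell_spec(ss_base_rate = 5, cs_bout_start_gain = 5),
                          lt, seed = seed + 50)
    rs <- bout_transition_response(cell$cs_times, bouts, "start",
                                   session_duration = 300)
    re <- bout_transition_response(cell$cs_times, bouts, "end",
                                   session_duration = 300)
    hits_start <- hits_start + rs$significant
    hits_end <- hits_end + re$significant
  }
  expect_gte(hits_start, 5)  # gain present at the start ...
  expect_lte(hits_end, 1)    # ... and absent at the end
})

test_that("absent spikes in the response window give a negative, non-significant Z", {
  # complex spikes confined to the baseline period of each bout start
  starts <- seq(10, 300, by = 10)
  bouts <- data.frame(first_lick_index = seq_along(starts),
                      last_lick_index = seq_along(starts),
                      start_time = starts, end_time = starts + 1,
                      n_licks = 1L)
  cs <- sort(c(starts - 0.9, starts - 0.8, starts - 0.65, starts - 0.72))
  res <- bout_transition_response(cs, bouts, "start", session_duration = 310)
  expect_lt(res$peak_z, 0)
  expect_false(res$significant)
})

test_that("complex-spike-preceded licks carry fewer simple spikes", {
  worse <- 0
  for (seed in 1:5) {
    lt <- generate_licks(behaviour_spec(), duration = 300, seed = seed)
    cell <- generate_cell(cell_spec(cs_base_rate = 3, cs_pause = 0.030),
                          lt, seed = seed + 10)
    res <- cs_conditioned_licks(cell, lt)
    expect_false(res$incomplete)
    worse <- worse + (res$mean_z_pre_with < res$mean_z_pre_without)
  }
  expect_gte(worse, 4)
})

test_that("a cell without complex spikes yields a flagged single group", {
  lt <- generate_licks(behaviour_spec(), duration = 60, seed = 2)
  cell <- generate_cell(cell_spec(cs_base_rate = 0), lt, seed = 3)
  res <- cs_conditioned_licks(cell, lt)
  expect_true(res$incomplete)
  expect_null(res$psth_with)
})
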