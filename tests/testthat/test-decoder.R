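test_that("CV2 follows the pairwise formula", {
  expect_equal(cv2_series(rep(0.02, 10)), rep(0, 9))
  expect_equal(cv2_series(c(0.010, 0.030)), 1.0)
  expect_equal(cv2_series(0.02), numeric(0))
  expect_error(cv2_series(c(0.01, -0.01)), "positive")
  # alternating short/long intervals approach the upper bound
  expect_true(all(cv2_series(rep(c(0.001, 0.1), 10)) > 1.9))
})

test_that("mean CV2 of an exponential ISI train approaches 1", {
  set.seed(81)
  isi <- rexp(10000, 50)
  expect_equal(mean(cv2_series(isi)), 1, tolerance = 0.03)
})

test_that("window tiling uses a 190 ms stride from time zero", {
  cell <- cell_recording("c", ss_times = seq(0.005, 0.995, by = 0.01),
                         cs_times = 0.5)
  w <- extract_windows(cell, licks = 0.25, duration = 1.0)
  expect_equal(w$t_start, c(0, 0.19, 0.38, 0.57, 0.76))
  expect_equal(w$t_end - w$t_start, rep(0.2, 5))
  # the lick at 0.25 s labels exactly the windows containing it
  expect_equal(w$label, c("no_lick", "lick", rep("no_lick", 3)))
  expect_equal(w$ss_rate, rep(100, 5))
})

test_that("window features equal brute-force recomputation", {
  set.seed(82)
  for (i in 1:40) {
    dur <- runif(1, 3, 12)
    ss <- sort(runif(round(60 * dur), 0, dur))
    cs <- sort(runif(max(2, round(1.5 * dur)), 0, dur))
    lk <- sort(runif(round(2 * dur), 0, dur))
    cell <- cell_recording("r", unique(ss), unique(cs))
    got <- extract_windows(cell, lk, duration = dur, impute = FALSE)
    want <- oracle_window_features(unique(ss), unique(cs), lk, dur)
    want <- want[!is.na(want$ss_cv2), ]
    expect_equal(got$t_start, want$t_start)
    expect_equal(got$ss_rate, want$ss_rate)
    expect_equal(got$cs_rate, want$cs_rate)
    expect_equal(got$ss_cv2, want$ss_cv2)
    expect_equal(got$label, want$label)
  }
})

test_that("the balanced split follows the two-thirds-of-smaller rule", {
  w <- data.frame(ss_rate = rnorm(120), ss_cv2 = runif(120),
                  cs_rate = rnorm(120),
                  label = rep(c("lick", "no_lick"), c(30, 90)))
  sp <- balanced_split(w, seed = 5)
  expect_equal(sum(sp$train$label == "lick"), 20)
  expect_equal(sum(sp$train$label == "no_lick"), 20)
  expect_equal(nrow(sp$test), 80)

  # equal class sizes m: 2*floor(2m/3) training rows
  w2 <- w; w2$label <- rep(c("lick", "no_lick"), 60)
  sp2 <- balanced_split(w2, seed = 6)
  expect_equal(nrow(sp2$train), 2 * floor(2 * 60 / 3))

  # the training set is balanced whatever the seed
  for (s in 1:10) {
    sp3 <- balanced_split(w, seed = s)
    expect_equal(sum(sp3$train$label == "lick"),
                 sum(sp3$train$label == "no_lick"))
  }
})

test_that("a perfectly separable cell is decoded at 100%", {
  n <- 240
  w <- data.frame(ss_rate = rep(c(100, 10), n / 2),
                  ss_cv2 = rep(0.8, n), cs_rate = rep(1, n),
                  label = rep(c("lick", "no_lick"), n / 2))
  sp <- balanced_split(w, seed = 2)
  rep <- train_eval(sp$train, sp$test, nrounds = 30, seed = 2)
  expect_equal(rep$acc_bout, 100)
  expect_equal(rep$acc_interbout, 100)
  expect_equal(rep$predictivity, "strongly_predictive")
  expect_true(rep$degenerate)  # two features carry a single value
})

test_that("predictivity is a pure threshold function with strict bounds", {
  expect_equal(classify_predictivity(80, 80), "strongly_predictive")
  expect_equal(classify_predictivity(66, 65), "predictive")
  expect_equal(classify_predictivity(65, 65), "predictive")
  expect_equal(classify_predictivity(56, 60), "predictive")
  expect_equal(classify_predictivity(55, 80), "non_predictive")
  expect_equal(classify_predictivity(54, 54), "non_predictive")
})

test_that("attribution singles out the only informative feature", {
  set.seed(83)
  n <- 300
  lab <- rep(c("lick", "no_lick"), n / 2)
  w <- data.frame(ss_rate = rep(60, n),
                  ss_cv2 = ifelse(lab == "lick", 1.2, 0.6) + rnorm(n, 0, 0.05),
                  cs_rate = rep(1, n), label = lab)
  sp <- balanced_split(w, seed = 3)
  rep <- train_eval(sp$train, sp$test, nrounds = 60, seed = 3)
  expect_equal(names(which.max(rep$attribution)), "ss_cv2")
  expect_gt(rep$attribution["ss_cv2"], rep$attribution["ss_rate"])
  expect_gt(rep$attribution["ss_cv2"], rep$attribution["cs_rate"])
})
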