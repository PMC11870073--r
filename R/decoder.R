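# Gradient-boosted-tree decoding of lick versus no-lick epochs from
# 200 ms snippet features (SS rate, SS CV2, CS rate), with balanced
# train/test construction and Shapley-style feature attribution.

#' Local coefficient of variation (CV2) of an interspike-interval series
#'
#' `CV2_n = 2 |ISI_{n+1} - ISI_n| / (ISI_{n+1} + ISI_n)`, one value per
#' adjacent ISI pair, each in `[0, 2)`. The expectation is 0 for a perfectly
#' regular train and 1 for a Poisson train.
#'
#' @param isi numeric vector of positive interspike intervals (s).
#' @return numeric vector of length `length(isi) - 1` (empty if fewer than
#'   two ISIs).
#' @examples
#' cv2_series(c(0.010, 0.030))  # 1.0
#' @export
cv2_series <- function(isi) {
  if (length(isi) < 2) return(numeric(0))
  if (any(isi <= 0)) stop("interspike intervals must be positive")
  a <- isi[-length(isi)]
  b <- isi[-1]
  2 * abs(b - a) / (b + a)
}

#' Cut a session into 200 ms feature windows
#'
#' Consecutive windows share `overlap` seconds (default 10 ms, i.e. a 190 ms
#' stride starting from time 0). Each window carries the simple-spike rate,
#' the mean CV2 of the simple-spike ISI pairs whose middle spike falls in
#' the window, and the complex-spike rate, plus a `lick` label that is true
#' iff at least one lick detection falls inside the window. Events count
#' toward a window when they lie in `[t_start, t_end)`.
#'
#' Windows with fewer than 3 simple spikes (or no CV2-carrying middle spike)
#' have undefined CV2; it is imputed with the cell's median CV2 within the
#' same label class and flagged, which keeps the class balance intact
#' (`impute = FALSE` drops such windows instead).
#'
#' @param cell a [cell_recording()].
#' @param licks a [lick_train()] (or numeric lick times).
#' @param duration session length (s); defaults to the lick train's.
#' @param win window length (s). @param overlap shared length (s).
#' @param impute impute undefined CV2 (default) or drop those windows.
#' @return data frame of class `feature_windows`: `t_start, t_end, ss_rate,
#'   ss_cv2, cs_rate, label` (`"lick"`/`"no_lick"`), `cv2_imputed`.
#' @export
extract_windows <- function(cell, licks, duration = NULL, win = 0.200,
                            overlap = 0.010, impute = TRUE) {
  lick_times <- if (inherits(licks, "lick_train")) licks$detect_times else
    as.numeric(licks)
  if (is.null(duration)) {
    duration <- if (inherits(licks, "lick_train")) licks$session_duration else
      max(lick_times, cell$ss_times, cell$cs_times)
  }
  stride <- win - overlap
  n_win <- floor((duration - win) / stride + 1e-9) + 1
  if (n_win < 2) stop("session must be at least two windows long")
  t0 <- stride * (seq_len(n_win) - 1)
  count_in <- function(ev, lo, hi) {
    ev <- sort(ev)
    findInterval(hi, ev, left.open = TRUE) -
      findInterval(lo, ev, left.open = TRUE)
  }
  ss_n <- count_in(cell$ss_times, t0, t0 + win)
  cs_n <- count_in(cell$cs_times, t0, t0 + win)
  lick_n <- count_in(lick_times, t0, t0 + win)
  # CV2 values live on the middle spike of their ISI pair
  cv2_vals <- cv2_series(diff(cell$ss_times))
  mid_spikes <- cell$ss_times[seq_along(cv2_vals) + 1L]
  cv2 <- rep(NA_real_, n_win)
  if (length(cv2_vals)) {
    wi <- floor(mid_spikes / stride) + 1L       # candidate window(s)
    for (k in c(0L, -1L)) {                     # overlap: spike can sit in two
      w <- wi + k
      ok <- w >= 1 & w <= n_win & mid_spikes >= t0[pmax(w, 1)] &
        mid_spikes < t0[pmax(w, 1)] + win
      if (any(ok)) {
        sums <- tapply(cv2_vals[ok], w[ok], sum)
        cnts <- tapply(rep(1, sum(ok)), w[ok], sum)
        idx <- as.integer(names(sums))
        add <- rep(0, n_win); cnt <- rep(0, n_win)
        add[idx] <- sums; cnt[idx] <- cnts
        if (k == 0L) { cv2_sum <- add; cv2_cnt <- cnt }
        else { cv2_sum <- cv2_sum + add; cv2_cnt <- cv2_cnt + cnt }
      } else if (k == 0L) { cv2_sum <- rep(0, n_win); cv2_cnt <- rep(0, n_win) }
    }
    have <- cv2_cnt > 0 & ss_n >= 3
    cv2[have] <- cv2_sum[have] / cv2_cnt[have]
  }
  out <- data.frame(t_start = t0, t_end = t0 + win,
                    ss_rate = ss_n / win, ss_cv2 = cv2, cs_rate = cs_n / win,
                    label = ifelse(lick_n > 0, "lick", "no_lick"),
                    cv2_imputed = is.na(cv2))
  if (impute) {
    for (lab in unique(out$label)) {
      sel <- out$label == lab
      med <- stats::median(out$ss_cv2[sel], na.rm = TRUE)
      if (!is.finite(med)) med <- stats::median(out$ss_cv2, na.rm = TRUE)
      out$ss_cv2[sel & is.na(out$ss_cv2)] <- med
    }
    out <- out[!is.na(out$ss_cv2), , drop = FALSE]
  } else {
    out <- out[!is.na(out$ss_cv2), , drop = FALSE]
  }
  class(out) <- c("feature_windows", "data.frame")
  out
}

#' Balanced train/test split of feature windows
#'
#' Draws `floor(frac * min(n_lick, n_no_lick))` windows without replacement
#' from each class for training; every remaining window goes to the test
#' set, so the training set is exactly balanced while the test set keeps the
#' natural class imbalance.
#'
#' @param windows an [extract_windows()] data frame.
#' @param frac training fraction of the smaller class (default 2/3).
#' @param seed integer RNG seed.
#' @return list `train`, `test` (both `feature_windows`), `n_train_per_class`.
#' @export
balanced_split <- function(windows, frac = 2 / 3, seed = 1) {
  i_lick <- which(windows$label == "lick")
  i_none <- which(windows$label == "no_lick")
  if (!length(i_lick) || !length(i_none)) stop("both classes must be non-empty")
  n <- floor(frac * min(length(i_lick), length(i_none)))
  if (n < 1) stop("too few windows for a balanced training set")
  set.seed(seed)
  tr <- c(sample(i_lick, n), sample(i_none, n))
  list(train = windows[tr, , drop = FALSE],
       test = windows[-tr, , drop = FALSE],
       n_train_per_class = n)
}

decoder_features <- c("ss_rate", "ss_cv2", "cs_rate")

#' Train and evaluate the lick decoder
#'
#' Fits a gradient-boosted decision-tree ensemble (XGBoost; histogram-based
#' split finding, 4096 trees of depth 8 by default) on the three snippet
#' features and reports per-class test accuracy, the predictivity class
#' (`predictive` iff both accuracies exceed 55%, `strongly_predictive` iff
#' both exceed 65%; boundary values do not qualify) and per-feature
#' attribution, the mean absolute Shapley-additive contribution per test
#' window.
#'
#' @param train,test `feature_windows` from [balanced_split()].
#' @param nrounds,max_depth,eta boosted-ensemble hyperparameters.
#' @param seed integer RNG seed (recorded in the report).
#' @return list of class `decoder_report`: `acc_bout`, `acc_interbout` (%),
#'   `predictivity`, `attribution` (named, mean |SHAP|), `n_train_per_class`,
#'   `n_test`, `degenerate`, `seed`.
#' @export
train_eval <- function(train, test, nrounds = 4096, max_depth = 8, eta = 0.3,
                       seed = 1) {
  xtr <- as.matrix(train[, decoder_features])
  xte <- as.matrix(test[, decoder_features])
  ytr <- as.numeric(train$label == "lick")
  yte <- as.numeric(test$label == "lick")
  degenerate <- any(apply(xtr, 2, function(v) length(unique(v)) == 1))
  set.seed(seed)
  dtr <- xgboost::xgb.DMatrix(xtr, label = ytr)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, tree_method = "hist", nthread = 1,
                  seed = seed),
    data = dtr, nrounds = nrounds, verbose = 0)
  dte <- xgboost::xgb.DMatrix(xte, label = yte)
  pred <- as.numeric(predict(fit, dte) > 0.5)
  acc_bout <- 100 * mean(pred[yte == 1] == 1)
  acc_interbout <- 100 * mean(pred[yte == 0] == 0)
  contrib <- predict(fit, dte, predcontrib = TRUE)
  attribution <- colMeans(abs(contrib[, decoder_features, drop = FALSE]))
  structure(list(acc_bout = acc_bout, acc_interbout = acc_interbout,
                 predictivity = classify_predictivity(acc_bout, acc_interbout),
                 attribution = attribution,
                 n_train_per_class = sum(ytr == 1), n_test = nrow(test),
                 degenerate = degenerate, seed = seed),
            class = "decoder_report")
}

#' Predictivity class from the two per-class accuracies
#'
#' Pure function of the accuracies: both > 65% gives `strongly_predictive`,
#' both > 55% (but not both > 65%) gives `predictive`, anything else
#' `non_predictive`; exact boundary values do not qualify.
#'
#' @param acc_bout,acc_interbout per-class accuracies in percent.
#' @export
classify_predictivity <- function(acc_bout, acc_interbout) {
  if (acc_bout > 65 && acc_interbout > 65) return("strongly_predictive")
  if (acc_bout > 55 && acc_interbout > 55) return("predictive")
  "non_predictive"
}

#' @export
print.decoder_report <- function(x, ...) {
  cat(sprintf("<decoder> bout %.1f%%, inter-bout %.1f%% -> %s\n",
              x$acc_bout, x$acc_interbout, x$predictivity))
  cat("  mean |SHAP|:",
      paste(sprintf("%s %.3f", names(x$attribution), x$attribution),
            collapse = ", "), "\n")
  invisible(x)
}

#' Decode one cell end to end
#'
#' Convenience wrapper: [extract_windows()], [balanced_split()],
#' [train_eval()].
#'
#' @param cell a [cell_recording()]. @param licks a [lick_train()].
#' @param seed RNG seed governing split and model.
#' @param nrounds,max_depth tree-ensemble size.
#' @export
decode_cell <- function(cell, licks, seed = 1, nrounds = 4096, max_depth = 8) {
  w <- extract_windows(cell, licks)
  sp <- balanced_split(w, seed = seed)
  train_eval(sp$train, sp$test, nrounds = nrounds, max_depth = max_depth,
             seed = seed)
}
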