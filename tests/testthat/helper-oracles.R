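# Brute-force reference implementations used for oracle-equivalence tests.
# These deliberately use naive loops and stay independent of the package's
# vectorised code paths.

oracle_bouts <- function(t, max_gap = 0.5) {
  if (!length(t)) {
    return(data.frame(first_lick_index = integer(), last_lick_index = integer(),
                      start_time = numeric(), end_time = numeric(),
                      n_licks = integer()))
  }
  first <- 1L
  rows <- list()
  for (i in seq_along(t)) {
    last_of_bout <- i == length(t) || (t[i + 1] - t[i]) >= max_gap
    if (last_of_bout) {
      rows[[length(rows) + 1]] <- data.frame(
        first_lick_index = first, last_lick_index = i,
        start_time = t[first], end_time = t[i], n_licks = i - first + 1L)
      first <- i + 1L
    }
  }
  do.call(rbind, rows)
}

oracle_psth_counts <- function(events, aligns, window, bin,
                               session_duration = NULL) {
  nb <- floor((window[2] - window[1]) / bin + 1e-9)
  counts <- numeric(nb)
  for (a in aligns) {
    if (!is.null(session_duration) &&
        (a + window[1] < 0 || a + window[1] + nb * bin > session_duration)) next
    for (e in events) {
      rel <- e - a
      for (b in seq_len(nb)) {
        lo <- window[1] + (b - 1) * bin
        if (rel >= lo && rel < lo + bin) counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

oracle_window_features <- function(ss, cs, lick_times, duration,
                                   win = 0.2, overlap = 0.01) {
  stride <- win - overlap
  n_win <- floor((duration - win) / stride + 1e-9) + 1
  cv2 <- licklock::cv2_series(diff(ss))
  mids <- ss[seq_along(cv2) + 1L]
  out <- list()
  for (w in seq_len(n_win)) {
    lo <- stride * (w - 1); hi <- lo + win
    in_w <- function(v) v >= lo & v < hi
    vals <- cv2[in_w(mids)]
    out[[w]] <- data.frame(
      t_start = lo,
      ss_rate = sum(in_w(ss)) / win,
      cs_rate = sum(in_w(cs)) / win,
      ss_cv2 = if (length(vals) && sum(in_w(ss)) >= 3) mean(vals) else NA_real_,
      label = if (any(in_w(lick_times))) "lick" else "no_lick")
  }
  do.call(rbind, out)
}

oracle_grid_summary <- function(values, grid_row, grid_col) {
  g <- array(NA_real_, c(8, 4))
  n <- array(0, c(8, 4))
  for (i in seq_along(values)) {
    if (is.na(values[i])) next
    r <- grid_row[i]; c <- grid_col[i]
    g[r, c] <- if (n[r, c] > 0) g[r, c] + values[i] else values[i]
    n[r, c] <- n[r, c] + 1
  }
  g <- g / ifelse(n > 0, n, NA)
  out <- matrix(NA_real_, 7, 3)
  for (i in 1:7) for (j in 1:3) {
    vals <- c(g[i, j], g[i, j + 1], g[i + 1, j], g[i + 1, j + 1])
    if (any(!is.na(vals))) out[i, j] <- mean(vals, na.rm = TRUE)
  }
  out
}

# naive scan: for every movement event, lick 0 is the last lick at or before
# it; licks 1..n_follow are the detections after it and before the next event
oracle_index_licks <- function(event_times, lick_times, n_follow = 3) {
  ord <- order(event_times)
  event_times <- event_times[ord]
  rows <- list()
  for (r in seq_along(event_times)) {
    e <- event_times[r]
    nxt <- if (r < length(event_times)) event_times[r + 1] else Inf
    before <- which(lick_times <= e)
    after <- which(lick_times > e & lick_times < nxt)
    if (!length(after)) next
    ks <- utils::head(after, n_follow)
    li <- seq_along(ks)
    if (length(before)) {
      ks <- c(max(before), ks)
      li <- c(0L, li)
    }
    rows[[length(rows) + 1]] <- data.frame(event = r, lick_index = li,
                                           lick = ks)
  }
  do.call(rbind, rows)
}

# deterministic lick train: bouts of `size` licks with period `T`, bouts
# `gap` seconds apart
comb_licks <- function(n_bouts = 30, size = 8, T = 0.16, gap = 2,
                       duration = NULL, endpoint_x = NULL, endpoint_y = NULL) {
  det <- unlist(lapply(seq_len(n_bouts) - 1,
                       function(b) b * (size * T + gap) + T * (0:(size - 1))))
  if (is.null(duration)) duration <- max(det) + 1
  lick_train(det, session_duration = duration,
             endpoint_x = endpoint_x, endpoint_y = endpoint_y,
             max_protrusion_times = det + 0.016)
}
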