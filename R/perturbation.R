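# Moving lick-port and optogenetic trial analyses: lick indexing around
# target movements, coordinate normalization, complex-spike movement
# responses and direction selectivity, simple-spike adaptation peaks, and
# optogenetic effect estimation.
#
# The closed-loop protocol moves the port 3 mm rightward 40 ms after a
# randomly selected lick (travel 50 ms), returns it 750 ms later, and waits
# at least another 750 ms before re-arming; the return is analysed as the
# centreward movement with the same machinery.

# rightward onsets + centreward returns as one ordered event table
port_event_table <- function(port_trials) {
  ev <- rbind(
    data.frame(time = port_trials$move_onset_s, direction = "rightward",
               trial = seq_len(nrow(port_trials))),
    data.frame(time = port_trials$return_s %||%
                 (port_trials$move_onset_s + 0.750),
               direction = "centreward", trial = seq_len(nrow(port_trials))))
  ev[order(ev$time), , drop = FALSE]
}

#' Index licks around lick-port movements
#'
#' For every movement event (rightward onset or centreward return), lick 0
#' is the last detection before the event and lick k (k = 1..3) the k-th
#' detection after it; indexing is truncated at the next movement event.
#' Licks that stayed at least 300 ms clear of any movement's 1.5 s trial
#' span serve as the baseline set.
#'
#' @param port_trials data frame of port trials (`move_onset_s`, `direction`,
#'   `displacement_mm`, optionally `return_s`).
#' @param licks a [lick_train()].
#' @param n_follow number of post-movement licks to index (default 3).
#' @param baseline_clear clearance required after a trial span for a
#'   baseline lick (s).
#' @return list of class `trial_lick_set`: `indexed` (data frame `event_id,
#'   direction, event_time, lick_index (0..n_follow), lick, t, x, y`),
#'   `baseline_licks` (global lick indices), `n_excluded` (events with no
#'   subsequent lick before truncation).
#' @export
index_trial_licks <- function(port_trials, licks, n_follow = 3,
                              baseline_clear = 0.300) {
  ev <- port_event_table(port_trials)
  t <- licks$detect_times
  x <- licks$endpoint_x; y <- licks$endpoint_y
  rows <- list(); excluded <- 0L
  for (r in seq_len(nrow(ev))) {
    e <- ev$time[r]
    nxt <- if (r < nrow(ev)) ev$time[r + 1] else Inf
    i0 <- findInterval(e, t)              # last lick at or before the event
    ks <- which(t > e & t < nxt)
    ks <- ks[seq_len(min(n_follow, length(ks)))]
    if (!length(ks)) { excluded <- excluded + 1L; next }
    idx <- c(if (i0 >= 1) i0 else NULL, ks)
    li <- c(if (i0 >= 1) 0L else NULL, seq_along(ks))
    rows[[r]] <- data.frame(
      event_id = r, direction = ev$direction[r], event_time = e,
      lick_index = li, lick = idx, t = t[idx],
      x = if (is.null(x)) NA_real_ else x[idx],
      y = if (is.null(y)) NA_real_ else y[idx])
  }
  indexed <- do.call(rbind, rows)
  if (is.null(indexed)) {
    indexed <- data.frame(event_id = integer(), direction = character(),
                          event_time = numeric(), lick_index = integer(),
                          lick = integer(), t = numeric(), x = numeric(),
                          y = numeric())
  }
  onsets <- port_trials$move_onset_s
  span <- 1.5 + baseline_clear
  affected <- rep(FALSE, length(t))
  for (o in onsets) affected <- affected | (t >= o & t < o + span)
  structure(list(indexed = indexed,
                 baseline_licks = which(!affected),
                 event_times = ev$time,
                 n_excluded = excluded),
            class = "trial_lick_set")
}

#' @export
print.trial_lick_set <- function(x, ...) {
  cat(sprintf("<trial_lick_set> %d indexed rows, %d baseline licks, %d events excluded\n",
              nrow(x$indexed), length(x$baseline_licks), x$n_excluded))
  invisible(x)
}

#' Normalize trial lick coordinates to the pre-movement position
#'
#' Per movement event, subtracts the mean endpoint of the pre-movement
#' reference licks — lick 0 together with the licks in the `ref_span`
#' seconds before the event — from all indexed licks of that event. The
#' default span of 0.75 s is the period the port is guaranteed to have held
#' its previous position, so reference licks cannot still be adapting to an
#' earlier movement. Normalizing already-normalized coordinates changes
#' nothing.
#'
#' @param trial_licks an [index_trial_licks()] result.
#' @param licks the same [lick_train()].
#' @param ref_span look-back span for reference licks before the event (s).
#' @return the `trial_lick_set` with `norm_x`, `norm_y` columns added to
#'   `indexed`.
#' @export
normalize_trial_coordinates <- function(trial_licks, licks, ref_span = 0.75) {
  ind <- trial_licks$indexed
  if (!nrow(ind)) return(trial_licks)
  if (all(is.na(ind$x))) stop("no endpoint coordinates to normalize")
  t <- licks$detect_times
  x <- licks$endpoint_x; y <- licks$endpoint_y
  ind$norm_x <- NA_real_; ind$norm_y <- NA_real_
  for (e in unique(ind$event_id)) {
    sel <- ind$event_id == e
    i0 <- ind$lick[sel & ind$lick_index == 0]
    if (!length(i0)) next
    ev_t <- ind$event_time[sel][1]
    ref <- unique(c(which(t >= ev_t - ref_span & t <= ev_t), i0))
    ref <- ref[ref <= i0]
    # prefer references settled for >= ref_span after any earlier movement;
    # when none exist (the return of the port's own trial) use them all
    all_ev <- unique(trial_licks$event_times %||% ind$event_time)
    settled <- ref[vapply(ref, function(j)
      !any(all_ev < t[j] & all_ev > t[j] - ref_span), TRUE)]
    if (length(settled)) ref <- settled
    ind$norm_x[sel] <- ind$x[sel] - mean(x[ref])
    ind$norm_y[sel] <- ind$y[sel] - mean(y[ref])
  }
  trial_licks$indexed <- ind
  trial_licks
}

#' Mean normalized displacement per lick index and direction
#'
#' @param trial_licks a normalized [index_trial_licks()] result.
#' @return data frame `direction, lick_index, mean_x, sd_x, se_x, mean_y, n`.
#' @export
adaptation_summary <- function(trial_licks) {
  ind <- trial_licks$indexed
  if (!"norm_x" %in% names(ind)) stop("run normalize_trial_coordinates() first")
  out <- list()
  for (d in unique(ind$direction)) for (k in sort(unique(ind$lick_index))) {
    sel <- ind$direction == d & ind$lick_index == k & !is.na(ind$norm_x)
    if (!any(sel)) next
    v <- ind$norm_x[sel]
    out[[length(out) + 1]] <- data.frame(
      direction = d, lick_index = k, mean_x = mean(v), sd_x = stats::sd(v),
      se_x = stats::sd(v) / sqrt(length(v)),
      mean_y = mean(ind$norm_y[sel]), n = length(v))
  }
  do.call(rbind, out)
}

#' Complex-spike response to lick-port movements
#'
#' CS PSTH aligned on movement events of one direction, Z-scored against the
#' 500 ms baseline preceding bout onsets (the same baseline convention as
#' for lick-timing modulation). A cell is responsive when the firing
#' increase over the response window exceeds `Z = 3` ([window_mean_z()]);
#' the peak-bin Z is reported as the response amplitude.
#'
#' @param cell a [cell_recording()].
#' @param port_trials the port trial table.
#' @param bouts a [segment_bouts()] table (anchors the baseline).
#' @param direction `"rightward"` or `"centreward"`.
#' @param min_trials minimum events per direction (default 20).
#' @param response_window window after the event searched for the peak (s).
#' @param session_duration session length (s).
#' @return a `modulation_result` with `peak_z`, `responsive`, `psth`.
#' @export
cs_move_response <- function(cell, port_trials, bouts,
                             direction = c("rightward", "centreward"),
                             min_trials = 20, response_window = c(0, 0.3),
                             session_duration = NULL) {
  direction <- match.arg(direction)
  ev <- port_event_table(port_trials)
  align <- ev$time[ev$direction == direction]
  if (length(align) < min_trials) {
    stop("too few ", direction, " events (", length(align), " < ", min_trials, ")")
  }
  base_psth <- compute_psth(cell$cs_times, bouts$start_time,
                            window = c(-1.0, 0), bin = 0.010,
                            session_duration = session_duration)
  inb <- psth_bin_in(base_psth, c(-1.0, -0.5))
  stats_bl <- list(mean = mean(base_psth$rate[inb]),
                   sd = stats::sd(base_psth$rate[inb]))
  p <- compute_psth(cell$cs_times, align, window = c(-0.5, 0.5), bin = 0.010,
                    session_duration = session_duration)
  p <- zscore_psth(p, baseline_stats = stats_bl)
  inr <- psth_bin_in(p, response_window)
  peak <- if (p$zero_sd) NA_real_ else max(p$z[inr])
  mz <- window_mean_z(p, response_window)
  structure(list(direction = direction, peak_z = peak, mean_z = mz,
                 responsive = isTRUE(mz > 3), psth = p,
                 n_events = length(align)),
            class = "cs_move_result")
}

#' @export
print.cs_move_result <- function(x, ...) {
  cat(sprintf("<cs_move> %s: peak Z %.2f, %sresponsive (%d events)\n",
              x$direction, x$peak_z, if (x$responsive) "" else "not ",
              x$n_events))
  invisible(x)
}

#' Direction selectivity of the complex-spike movement response
#'
#' `peak_z(rightward) - peak_z(centreward)`; positive values mean a stronger
#' response to ipsiversive target movements.
#'
#' @inheritParams cs_move_response
#' @export
cs_move_selectivity <- function(cell, port_trials, bouts, min_trials = 20,
                                session_duration = NULL) {
  r <- cs_move_response(cell, port_trials, bouts, "rightward",
                        min_trials = min_trials,
                        session_duration = session_duration)
  c_ <- cs_move_response(cell, port_trials, bouts, "centreward",
                         min_trials = min_trials,
                         session_duration = session_duration)
  list(selectivity = r$peak_z - c_$peak_z, rightward = r, centreward = c_)
}

#' Simple-spike peaks around post-movement licks
#'
#' For each lick index (0..3) and movement direction, builds the SS PSTH
#' aligned on the maximal protrusion of those licks, Z-scored against the
#' 750 ms per-lick baseline (-1000 to -250 ms before detection), and takes
#' the peak Z within the protraction window (-75 to 0 ms before maximal
#' protrusion).
#'
#' @param cell a [cell_recording()].
#' @param trial_licks an [index_trial_licks()] result.
#' @param licks the session [lick_train()].
#' @param min_per_index minimum licks per (direction, index) cell.
#' @param peak_window protraction window relative to maximal protrusion (s).
#' @return data frame `direction, lick_index, peak_z, mean_z, n`.
#' @export
ss_adaptation_peaks <- function(cell, trial_licks, licks, min_per_index = 10,
                                peak_window = c(-0.075, 0)) {
  ind <- trial_licks$indexed
  t_det <- licks$detect_times
  t_max <- max_protrusion(licks)
  delay <- mean(t_max - t_det)
  out <- list()
  for (d in unique(ind$direction)) for (k in sort(unique(ind$lick_index))) {
    gl <- ind$lick[ind$direction == d & ind$lick_index == k]
    if (length(gl) < min_per_index) next
    base <- per_lick_baseline(cell$ss_times, t_det[gl])
    mu <- mean(base); sdv <- stats::sd(base)
    p <- compute_psth(cell$ss_times, t_max[gl], window = c(-0.3, 0.1),
                      bin = 0.010, session_duration = licks$session_duration)
    p <- zscore_psth(p, baseline_stats = list(mean = mu, sd = sdv))
    inw <- psth_bin_in(p, peak_window)
    out[[length(out) + 1]] <- data.frame(
      direction = d, lick_index = k,
      peak_z = if (p$zero_sd) NA_real_ else max(p$z[inw]),
      mean_z = if (p$zero_sd) NA_real_ else mean(p$z[inw]),
      n = length(gl))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(direction = character(),
                                      lick_index = integer(),
                                      peak_z = numeric(), mean_z = numeric(),
                                      n = integer())
  attr(res, "protraction_delay") <- delay
  res
}

#' Compare rightward and centreward SS peaks per lick index
#'
#' Paired Wilcoxon tests on per-cell peak values across a cohort, with
#' Benjamini-Hochberg correction across lick indices. Standard routines do
#' the testing; this helper only assembles the table.
#'
#' @param peaks data frame binding rows of [ss_adaptation_peaks()] over
#'   cells, with a `cell_id` column.
#' @return data frame `lick_index, p_raw, p_bh, n_cells`.
#' @export
compare_direction_peaks <- function(peaks) {
  idx <- sort(unique(peaks$lick_index))
  p_raw <- sapply(idx, function(k) {
    r <- peaks[peaks$lick_index == k & peaks$direction == "rightward", ]
    c_ <- peaks[peaks$lick_index == k & peaks$direction == "centreward", ]
    m <- merge(r, c_, by = "cell_id")
    if (nrow(m) < 3) return(NA_real_)
    stats::wilcox.test(m$peak_z.x, m$peak_z.y, paired = TRUE, exact = FALSE)$p.value
  })
  data.frame(lick_index = idx, p_raw = p_raw,
             p_bh = stats::p.adjust(p_raw, method = "BH"),
             n_cells = sapply(idx, function(k)
               sum(peaks$lick_index == k & peaks$direction == "rightward")))
}

#' Optogenetic effect on tongue endpoints
#'
#' For each stimulation trial, licks 1..3 are the detections following pulse
#' onset; for each control lick (a "lick 0" unaffected by stimulation),
#' licks 1..3 are the following detections. The effect is the difference of
#' group means (stimulated minus control), per lick index, pulse-timing
#' condition and fibre; positive `dx` is rightward (ipsiversive for
#' right-side fibres), negative `dy` a shortened protrusion.
#'
#' @param licks a [lick_train()] with endpoints.
#' @param opto_trials data frame `trigger_lick_idx, onset_offset_s,
#'   duration_s, fibre`.
#' @param control_licks global indices of unstimulated reference licks.
#' @param n_follow number of post-onset licks to test.
#' @return data frame `fibre, onset_offset_s, duration_s, lick_index, dx,
#'   dy, n_stim, n_control`.
#' @export
opto_effect <- function(licks, opto_trials, control_licks, n_follow = 3) {
  if (!length(control_licks)) stop("no control licks supplied")
  t <- licks$detect_times
  x <- licks$endpoint_x; y <- licks$endpoint_y
  if (is.null(x) || is.null(y)) stop("endpoints required")
  follow_of <- function(i0) {
    ks <- which(t > t[i0])
    ks[seq_len(min(n_follow, length(ks)))]
  }
  ctrl <- lapply(control_licks, follow_of)
  ctrl_x <- ctrl_y <- matrix(NA_real_, length(ctrl), n_follow)
  for (i in seq_along(ctrl)) {
    ks <- ctrl[[i]]
    if (length(ks)) {
      ctrl_x[i, seq_along(ks)] <- x[ks]
      ctrl_y[i, seq_along(ks)] <- y[ks]
    }
  }
  out <- list()
  conds <- unique(opto_trials[, c("fibre", "onset_offset_s", "duration_s")])
  for (r in seq_len(nrow(conds))) {
    sel <- opto_trials$fibre == conds$fibre[r] &
      opto_trials$onset_offset_s == conds$onset_offset_s[r] &
      opto_trials$duration_s == conds$duration_s[r]
    trig <- opto_trials$trigger_lick_idx[sel]
    onset <- t[trig] + opto_trials$onset_offset_s[sel]
    for (k in seq_len(n_follow)) {
      kx <- ky <- rep(NA_real_, length(trig))
      for (i in seq_along(trig)) {
        ks <- which(t > onset[i])
        if (length(ks) >= k) { kx[i] <- x[ks[k]]; ky[i] <- y[ks[k]] }
      }
      out[[length(out) + 1]] <- data.frame(
        fibre = conds$fibre[r], onset_offset_s = conds$onset_offset_s[r],
        duration_s = conds$duration_s[r], lick_index = k,
        dx = mean(kx, na.rm = TRUE) - mean(ctrl_x[, k], na.rm = TRUE),
        dy = mean(ky, na.rm = TRUE) - mean(ctrl_y[, k], na.rm = TRUE),
        n_stim = sum(!is.na(kx)), n_control = sum(!is.na(ctrl_x[, k])))
    }
  }
  do.call(rbind, out)
}
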