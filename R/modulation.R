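# PSTH construction, baseline Z-scoring, modulation depth, complex-spike
# responses at bout transitions and the CS-conditioned lick analysis.
#
# Z-scores are (value - baseline mean) / baseline SD. Three baseline
# conventions are used, depending on the alignment: -1000..-500 ms before
# bout onset, +500..+1000 ms after bout end, and -1000..-250 ms before the
# licks of interest.

#' Peri-stimulus time histogram
#'
#' Events are pooled over alignment events into bins of `bin` seconds on the
#' given window. Alignment events whose window crosses the session edges are
#' dropped entirely (no per-bin correction).
#'
#' @param event_times numeric event times (s).
#' @param align_times numeric alignment event times (s).
#' @param window length-2 window relative to alignment (s).
#' @param bin bin width (s), default 0.010.
#' @param session_duration session length used for edge exclusion; `NULL`
#'   disables edge exclusion.
#' @return object of class `psth`: `edges`, `counts`, `rate` (Hz), `z`
#'   (`NULL` until [zscore_psth()]), `n_align`, `bin`, `baseline_window`.
#' @export
compute_psth <- function(event_times, align_times, window = c(-1, 1),
                         bin = 0.010, session_duration = NULL) {
  stopifnot(length(window) == 2, window[2] > window[1])
  nb <- floor((window[2] - window[1]) / bin + 1e-9)
  if (nb < 1) stop("window does not cover a single bin")
  edges <- window[1] + bin * (0:nb)
  if (!is.null(session_duration)) {
    keep <- (align_times + edges[1] >= 0) &
      (align_times + edges[nb + 1] <= session_duration)
    align_times <- align_times[keep]
  }
  if (!length(align_times)) stop("no usable alignment events")
  ev <- sort(event_times)
  counts <- numeric(nb)
  for (a in align_times) {
    lo <- findInterval(a + edges[1], ev, left.open = TRUE) + 1L
    hi <- findInterval(a + edges[nb + 1], ev, left.open = TRUE)
    if (hi < lo) next
    bi <- floor((ev[lo:hi] - a - edges[1]) / bin) + 1L
    bi <- bi[bi >= 1 & bi <= nb]
    if (length(bi)) counts <- counts + tabulate(bi, nbins = nb)
  }
  structure(list(edges = edges, counts = counts,
                 rate = counts / (length(align_times) * bin),
                 z = NULL, n_align = length(align_times), bin = bin,
                 baseline_window = NULL, zero_sd = FALSE),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins of %.0f ms, %d alignments, %s\n",
              length(x$counts), x$bin * 1000, x$n_align,
              if (is.null(x$z)) "not Z-scored" else
                sprintf("Z-scored on (%.3f, %.3f) s", x$baseline_window[1],
                        x$baseline_window[2])))
  invisible(x)
}

psth_bin_in <- function(psth, window) {
  lef <- psth$edges[-length(psth$edges)]
  rig <- psth$edges[-1]
  lef >= window[1] - 1e-9 & rig <= window[2] + 1e-9
}

#' Z-score a PSTH against a baseline window
#'
#' `z[i] = (rate[i] - mean(baseline rates)) / sd(baseline rates)` over the
#' bins fully inside the baseline window. A baseline with zero SD leaves the
#' Z undefined and flags the PSTH (`zero_sd`); no SD floor is applied, so
#' such cells can be excluded from significance counts rather than silently
#' inflated.
#'
#' @param psth a [compute_psth()] object.
#' @param baseline_window length-2 window (s) relative to alignment; must lie
#'   inside the PSTH range and cover at least two bins.
#' @param baseline_stats optional list `(mean, sd)` to use instead of bins of
#'   this PSTH (for baselines anchored to a different alignment).
#' @return the PSTH with `z`, `baseline_window` and `zero_sd` filled in.
#' @export
zscore_psth <- function(psth, baseline_window = NULL, baseline_stats = NULL) {
  if (is.null(baseline_stats)) {
    inb <- psth_bin_in(psth, baseline_window)
    if (sum(inb) < 2) stop("baseline window must cover at least two bins")
    mu <- mean(psth$rate[inb])
    sdv <- stats::sd(psth$rate[inb])
  } else {
    mu <- baseline_stats$mean
    sdv <- baseline_stats$sd
  }
  if (!is.finite(sdv) || sdv == 0) {
    psth$z <- rep(NA_real_, length(psth$rate))
    psth$zero_sd <- TRUE
  } else {
    psth$z <- (psth$rate - mu) / sdv
    psth$zero_sd <- FALSE
  }
  psth$baseline_window <- baseline_window
  psth$baseline_mean <- mu
  psth$baseline_sd <- sdv
  psth
}

#' Modulation depth and peak Z within a window
#'
#' Depth is the difference between the maximum and minimum of the mean
#' modulation (Z if available, rate otherwise) within the analysis window
#' (default 200 ms centred on the alignment event). Significance is the
#' peak bin: `|z| > 3` within the window.
#'
#' @param psth a (possibly Z-scored) [compute_psth()] object.
#' @param window analysis window (s), default `c(-0.1, 0.1)`.
#' @return list of class `modulation_result`: `depth`, `peak_z` (signed
#'   value at the largest `|z|`), `significant`, `window`, `on_z`.
#' @export
modulation_depth <- function(psth, window = c(-0.1, 0.1)) {
  inb <- psth_bin_in(psth, window)
  if (!any(inb)) stop("window outside PSTH range")
  on_z <- !is.null(psth$z) && !psth$zero_sd
  v <- if (on_z) psth$z[inb] else psth$rate[inb]
  peak_z <- if (on_z) psth$z[inb][which.max(abs(psth$z[inb]))] else NA_real_
  structure(list(depth = max(v) - min(v), peak_z = peak_z,
                 significant = isTRUE(abs(peak_z) > 3),
                 window = window, on_z = on_z),
            class = "modulation_result")
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("<modulation> depth %.2f %s, peak Z %.2f, %ssignificant\n",
              x$depth, if (x$on_z) "Z" else "Hz", x$peak_z,
              if (isTRUE(x$significant)) "" else "not "))
  invisible(x)
}

#' Z-score of a window-mean rate against the baseline-bin distribution
#'
#' `(mean(window rates) - baseline mean) / (baseline SD / sqrt(n))`, with
#' `n` the number of bins in the window: the Z of the firing rate *in the
#' interval*, on the scale of its own standard error. For sparse (~1 Hz)
#' complex-spike trains this statistic is calibrated (false-positive rate
#' well below 5% at `Z > 3`), whereas the peak of the raw 10 ms bins is
#' not: the maximum of thirty skewed Poisson bins divided by a noisy
#' baseline SD exceeds 3 in 15-30% of null cells at realistic bout counts.
#'
#' @param psth a Z-scored [compute_psth()].
#' @param window analysis window (s).
#' @return the Z value (`NA` when the baseline SD was zero).
#' @export
window_mean_z <- function(psth, window) {
  inb <- psth_bin_in(psth, window)
  if (!any(inb)) stop("window outside PSTH range")
  if (isTRUE(psth$zero_sd) || is.null(psth$baseline_sd) ||
      !is.finite(psth$baseline_sd) || psth$baseline_sd == 0) return(NA_real_)
  (mean(psth$rate[inb]) - psth$baseline_mean) /
    (psth$baseline_sd / sqrt(sum(inb)))
}

#' Complex-spike response at bout transitions
#'
#' PSTH of complex spikes aligned on the first (or last) lick of each bout,
#' Z-scored against the bout-start baseline (-1.0 to -0.5 s) or the bout-end
#' baseline (+0.5 to +1.0 s). A cell signals the transition when the firing
#' increase over the 300 ms interval centred on the alignment exceeds
#' `Z = 3` ([window_mean_z()]); the peak-bin Z is reported as the response
#' amplitude.
#'
#' @param cs_times complex-spike times (s).
#' @param bouts a [segment_bouts()] table.
#' @param which `"start"` or `"end"`.
#' @param min_trials minimum number of bouts (default 20).
#' @param session_duration session length for edge exclusion (s).
#' @param response_halfwidth half-width of the centred analysis window (s).
#' @return a `modulation_result` with the underlying `psth` attached.
#' @export
bout_transition_response <- function(cs_times, bouts, which = c("start", "end"),
                                     min_trials = 20, session_duration = NULL,
                                     response_halfwidth = 0.150) {
  which <- match.arg(which)
  if (nrow(bouts) < min_trials) {
    stop("too few bouts (", nrow(bouts), " < ", min_trials, ")")
  }
  if (which == "start") {
    align <- bouts$start_time
    window <- c(-1.0, 0.5)
    baseline <- c(-1.0, -0.5)
  } else {
    align <- bouts$end_time
    window <- c(-0.5, 1.0)
    baseline <- c(0.5, 1.0)
  }
  p <- compute_psth(cs_times, align, window = window, bin = 0.010,
                    session_duration = session_duration)
  p <- zscore_psth(p, baseline)
  res <- modulation_depth(p, c(-response_halfwidth, response_halfwidth))
  # a transition response is an *increase* in complex-spike firing
  inb <- psth_bin_in(p, res$window)
  res$peak_z <- if (p$zero_sd) NA_real_ else max(p$z[inb])
  res$mean_z <- window_mean_z(p, res$window)
  res$significant <- isTRUE(res$mean_z > 3)
  res$psth <- p
  res$which <- which
  res
}

# per-lick baseline rates over the -1000..-250 ms pre-detection window;
# z of per-lick window rates is taken against the across-lick distribution
# of these baseline rates
per_lick_baseline <- function(event_times, detect_times,
                              baseline = c(-1.0, -0.25)) {
  ev <- sort(event_times)
  width <- baseline[2] - baseline[1]
  lo <- findInterval(detect_times + baseline[1], ev, left.open = TRUE)
  hi <- findInterval(detect_times + baseline[2], ev, left.open = TRUE)
  (hi - lo) / width
}

window_rates <- function(event_times, ref_times, window) {
  ev <- sort(event_times)
  lo <- findInterval(ref_times + window[1], ev, left.open = TRUE)
  hi <- findInterval(ref_times + window[2], ev, left.open = TRUE)
  (hi - lo) / (window[2] - window[1])
}

#' Licks conditioned on a preceding complex spike
#'
#' Splits licks into those preceded by at least one complex spike in the
#' `cs_window` (default 75 ms) before detection and those not, and contrasts
#' the two groups: per-group simple-spike PSTHs (Z-scored with the per-lick
#' baseline, -1000 to -250 ms before detection), the mean Z over the 150 ms
#' pre-detection interval, and per-group endpoint coordinates.
#'
#' @param cell a [cell_recording()].
#' @param licks a [lick_train()] (endpoints used when present).
#' @param cs_window look-back window for a conditioning complex spike (s).
#' @param psth_window PSTH window around detection (s).
#' @return list of class `conditioned_result`: `psth_with`, `psth_without`,
#'   `mean_z_pre_with`, `mean_z_pre_without`, per-group endpoint means and
#'   per-lick values, `incomplete` flag.
#' @export
cs_conditioned_licks <- function(cell, licks, cs_window = 0.075,
                                 psth_window = c(-0.4, 0.1)) {
  t <- licks$detect_times
  cs <- sort(cell$cs_times)
  hi <- findInterval(t, cs, left.open = TRUE)
  lo <- findInterval(t - cs_window, cs, left.open = TRUE)
  with_cs <- (hi - lo) > 0
  incomplete <- !any(with_cs) || all(with_cs)
  base_rates <- per_lick_baseline(cell$ss_times, t)
  pre_rates <- window_rates(cell$ss_times, t, c(-0.150, 0))
  group_psth <- function(sel) {
    if (sum(sel) < 2) return(NULL)
    mu <- mean(base_rates[sel]); sdv <- stats::sd(base_rates[sel])
    p <- compute_psth(cell$ss_times, t[sel], window = psth_window,
                      session_duration = licks$session_duration)
    zscore_psth(p, baseline_stats = list(mean = mu, sd = sdv))
  }
  zify <- function(sel) {
    mu <- mean(base_rates[sel]); sdv <- stats::sd(base_rates[sel])
    if (!is.finite(sdv) || sdv == 0) return(rep(NA_real_, sum(sel)))
    (pre_rates[sel] - mu) / sdv
  }
  mean_or_na <- function(v) if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  ex <- licks$endpoint_x; ey <- licks$endpoint_y
  structure(list(
    with_cs = with_cs,
    psth_with = group_psth(with_cs),
    psth_without = group_psth(!with_cs),
    mean_z_pre_with = mean_or_na(zify(with_cs)),
    mean_z_pre_without = mean_or_na(zify(!with_cs)),
    endpoint_x_with = if (is.null(ex)) NA_real_ else mean_or_na(ex[with_cs]),
    endpoint_x_without = if (is.null(ex)) NA_real_ else mean_or_na(ex[!with_cs]),
    endpoint_y_with = if (is.null(ey)) NA_real_ else mean_or_na(ey[with_cs]),
    endpoint_y_without = if (is.null(ey)) NA_real_ else mean_or_na(ey[!with_cs]),
    per_lick = data.frame(
      lick = seq_along(t), with_cs = with_cs,
      x = if (is.null(ex)) NA_real_ else ex,
      y = if (is.null(ey)) NA_real_ else ey),
    incomplete = incomplete), class = "conditioned_result")
}

#' Per-lick rhythmic modulation of a spike train
#'
#' PSTH aligned on lick detections, Z-scored with the per-lick baseline
#' (-1000 to -250 ms before the licks of interest) restricted to licks whose
#' baseline window contains no earlier bout activity, and summarised by
#' [modulation_depth()] over the 200 ms window centred on detection.
#'
#' Used for the per-cell "rhythmic modulation" flag; only licks that start a
#' bout have a bout-free baseline, so the alignment set is the bout-start
#' licks unless `all_licks = TRUE`.
#'
#' @param spike_times spike times (s).
#' @param licks a [lick_train()].
#' @param bouts optional [segment_bouts()] table.
#' @param all_licks align on every lick instead (baseline then overlaps the
#'   preceding licks of the bout).
#' @return a `modulation_result` with the PSTH attached.
#' @export
lick_modulation <- function(spike_times, licks, bouts = NULL,
                            all_licks = FALSE) {
  if (is.null(bouts)) bouts <- segment_bouts(licks)
  align <- if (all_licks) licks$detect_times else
    licks$detect_times[bouts$first_lick_index]
  p <- compute_psth(spike_times, align, window = c(-1.0, 0.5),
                    session_duration = licks$session_duration)
  p <- zscore_psth(p, c(-1.0, -0.25))
  res <- modulation_depth(p, c(-0.1, 0.1))
  res$psth <- p
  res
}
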