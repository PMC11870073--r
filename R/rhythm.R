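# Phase transform of the lick cycle, coherence at the lick fundamental,
# autocorrelogram power in and out of bouts, and the electrode-grid summary.

#' Build a piecewise-linear phase map of the lick cycle
#'
#' Each lick cycle is anchored at three moments: protrusion start (phase 0),
#' maximal protrusion (phase pi) and end of retraction (phase 2*pi). Maximal
#' protrusion comes from the recorded times (or detection + 16 ms); protrusion
#' start and retraction end are placed at the temporal midpoints between
#' neighbouring maximal protrusions within a bout, with bout-edge cycles
#' extended by the bout's mean half-cycle. Phase is linear on each half-cycle.
#'
#' Licks in single-lick bouts define no cycle and are masked.
#'
#' @param licks a [lick_train()].
#' @param bouts optional precomputed [segment_bouts()] table.
#' @param max_gap bout gap threshold (s) when `bouts` is not supplied.
#' @return object of class `phase_map`: a cycle table with columns
#'   `lick_index, bout, s, m, e` (anchor times).
#' @export
build_phase_map <- function(licks, bouts = NULL, max_gap = 0.5) {
  m_all <- max_protrusion(licks)
  if (is.null(bouts)) bouts <- segment_bouts(licks, max_gap)
  rows <- vector("list", nrow(bouts))
  for (b in seq_len(nrow(bouts))) {
    idx <- bouts$first_lick_index[b]:bouts$last_lick_index[b]
    if (length(idx) < 2) next
    m <- m_all[idx]
    half <- mean(diff(m)) / 2
    mids <- (m[-1] + m[-length(m)]) / 2
    s <- c(m[1] - half, mids)
    e <- c(mids, m[length(m)] + half)
    rows[[b]] <- data.frame(lick_index = idx, bout = b, s = s, m = m, e = e)
  }
  cycles <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(cycles)) {
    cycles <- data.frame(lick_index = integer(), bout = integer(),
                         s = numeric(), m = numeric(), e = numeric())
  }
  structure(list(cycles = cycles, n_licks = n_licks(licks)),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d cycles from %d licks\n",
              nrow(x$cycles), x$n_licks))
  invisible(x)
}

#' Evaluate lick-cycle phase at arbitrary times
#'
#' @param pm a [build_phase_map()] object.
#' @param t numeric times (s).
#' @return data frame `phase` (radians in `[0, 2*pi]`, `NA` outside any
#'   cycle), `cycle` (row index into the cycle table) and `bout`.
#' @export
phase_at <- function(pm, t) {
  cy <- pm$cycles
  phase <- rep(NA_real_, length(t))
  cycle <- rep(NA_integer_, length(t))
  bout <- rep(NA_integer_, length(t))
  if (nrow(cy)) {
    i <- findInterval(t, cy$s)
    ok <- i >= 1 & i <= nrow(cy)
    ok[ok] <- t[ok] <= cy$e[i[ok]]
    ii <- i[ok]; tt <- t[ok]
    asc <- tt <= cy$m[ii]
    ph <- numeric(length(tt))
    ph[asc] <- pi * (tt[asc] - cy$s[ii[asc]]) / (cy$m[ii[asc]] - cy$s[ii[asc]])
    ph[!asc] <- pi + pi * (tt[!asc] - cy$m[ii[!asc]]) /
      (cy$e[ii[!asc]] - cy$m[ii[!asc]])
    phase[ok] <- ph
    cycle[ok] <- ii
    bout[ok] <- cy$bout[ii]
  }
  data.frame(phase = phase, cycle = cycle, bout = bout)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

wrap_2pi <- function(x) x %% (2 * pi)

#' Spike-lick coherence on the warped (phase) axis
#'
#' Spike times are mapped through the lick-cycle phase map onto a warped axis
#' measured in lick cycles, which removes the timing jitter between
#' individual licks. On that axis the cross-correlogram between spikes and
#' lick events and the autocorrelogram of lick events are computed with
#' pairs restricted to the same bout, normalized by the pair-availability
#' envelope of the finite correlogram window, mean-removed and Hann-tapered.
#' Bouts are assigned round-robin to `n_blocks` blocks, each block
#' contributing one correlogram pair; cross- and auto-spectra are averaged
#' over blocks and the magnitude-squared coherence and cross-spectrum phase
#' are read at the lick fundamental (1 cycle^-1). The preferred firing phase
#' within the lick cycle is reported in the 0/pi/2*pi anchor convention.
#'
#' @param spike_times numeric spike times (s).
#' @param pm a [build_phase_map()] for the session's licks.
#' @param corr_window correlogram half-width in cycles (default 2).
#' @param bin correlogram bin width in cycles (default 0.02).
#' @param min_spikes minimum number of in-bout spikes required to classify
#'   a cell (default 100); below it the result is flagged low-power.
#' @param n_blocks number of bout blocks averaged over (default 8).
#' @return list of class `coherence_result`: `msc`, `phase` (preferred spike
#'   phase, radians in `[0, 2*pi)`), `coherent` (`msc > 0.5`), `n_spikes`,
#'   `low_power`.
#' @export
lick_coherence <- function(spike_times, pm, corr_window = 2, bin = 0.02,
                           min_spikes = 100, n_blocks = 8) {
  ph <- phase_at(pm, spike_times)
  ok <- !is.na(ph$phase)
  u_s <- ph$cycle[ok] - 1 + ph$phase[ok] / (2 * pi)
  b_s <- ph$bout[ok]
  n_spk <- length(u_s)
  cy <- pm$cycles
  u_l <- seq_len(nrow(cy)) - 1 + 0.5       # lick events sit at phase pi
  b_l <- cy$bout
  bout_ids <- unique(cy$bout)
  low_power <- n_spk < min_spikes || length(bout_ids) < n_blocks
  if (n_spk < 2 || length(bout_ids) < 2) {
    return(structure(list(msc = NA_real_, phase = NA_real_, coherent = NA,
                          n_spikes = n_spk, low_power = TRUE),
                     class = "coherence_result"))
  }
  # warped span [lo, hi] of each bout (contiguous cycles)
  span_lo <- tapply(seq_len(nrow(cy)) - 1, cy$bout, min)
  span_hi <- tapply(seq_len(nrow(cy)), cy$bout, max)
  block_of <- stats::setNames(
    (seq_along(bout_ids) - 1L) %% min(n_blocks, length(bout_ids)) + 1L,
    bout_ids)
  nb <- round(2 * corr_window / bin)
  centres <- -corr_window + bin * (seq_len(nb) - 0.5)
  span <- nb * bin
  k0 <- round(span) + 1L                   # DFT index of 1 cycle^-1
  taper <- hann_window(nb)
  sxy <- 0 + 0i; sxx <- 0; syy <- 0
  n_used <- 0L
  for (blk in seq_len(max(block_of))) {
    bts <- bout_ids[block_of == blk]
    sel_l <- b_l %in% bts
    sel_s <- b_s %in% bts
    if (!any(sel_l)) next
    xc <- warped_correlogram(u_s[sel_s], b_s[sel_s], u_l[sel_l], b_l[sel_l],
                             corr_window, bin)
    ac <- warped_correlogram(u_l[sel_l], b_l[sel_l], u_l[sel_l], b_l[sel_l],
                             corr_window, bin, exclude_self = TRUE)
    # pair-availability envelope: for each lick, lags staying inside the bout
    env <- numeric(nb)
    for (j in which(sel_l)) {
      lo <- as.numeric(span_lo[as.character(b_l[j])]) - u_l[j]
      hi <- as.numeric(span_hi[as.character(b_l[j])]) - u_l[j]
      i1 <- max(1L, ceiling((lo + corr_window) / bin + 0.5))
      i2 <- min(nb, floor((hi + corr_window) / bin + 0.5))
      if (i2 >= i1) env[i1:i2] <- env[i1:i2] + 1
    }
    pos <- env > 0
    if (sum(pos) < 4) next
    x <- numeric(nb); y <- numeric(nb)
    x[pos] <- xc[pos] / env[pos]
    y[pos] <- ac[pos] / env[pos]
    x <- (x - mean(x[pos])) * taper
    y <- (y - mean(y[pos])) * taper
    X <- stats::fft(x); Y <- stats::fft(y)
    sxy <- sxy + X[k0] * Conj(Y[k0])
    sxx <- sxx + Mod(X[k0])^2
    syy <- syy + Mod(Y[k0])^2
    n_used <- n_used + 1L
  }
  if (n_used < 2 || sxx == 0 || syy == 0) {
    return(structure(list(msc = NA_real_, phase = NA_real_, coherent = NA,
                          n_spikes = n_spk, low_power = TRUE),
                     class = "coherence_result"))
  }
  msc <- Mod(sxy)^2 / (sxx * syy)
  delta <- -Arg(sxy) / (2 * pi)            # lag of the spike comb, cycles
  phase <- wrap_2pi(pi + 2 * pi * delta)
  structure(list(msc = msc, phase = phase,
                 coherent = if (low_power) NA else isTRUE(msc > 0.5),
                 n_spikes = n_spk, low_power = low_power),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence> msc %.3f, phase %.2f rad, %s (%d spikes%s)\n",
              x$msc, x$phase,
              if (isTRUE(x$coherent)) "coherent" else "not coherent",
              x$n_spikes, if (x$low_power) ", LOW POWER" else ""))
  invisible(x)
}

# same-group pair correlogram on a warped or real axis
warped_correlogram <- function(a, ga, b, gb, w, bin, exclude_self = FALSE) {
  edges <- seq(-w, w, by = bin)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  ord <- order(a)
  a <- a[ord]; ga <- ga[ord]
  for (j in seq_along(b)) {
    lo <- findInterval(b[j] - w, a) + 1L
    hi <- findInterval(b[j] + w, a)
    if (hi < lo) next
    k <- lo:hi
    k <- k[ga[k] == gb[j]]
    if (exclude_self && length(k)) k <- k[a[k] != b[j]]
    if (!length(k)) next
    bi <- floor((a[k] - b[j] - edges[1]) / bin) + 1L
    bi <- bi[bi >= 1 & bi <= nb]
    if (length(bi)) counts <- counts + tabulate(bi, nbins = nb)
  }
  counts
}

#' Autocorrelogram power of simple spikes inside and outside bouts
#'
#' Simple-spike autocorrelograms are built separately from spikes inside
#' licking bouts and spikes between bouts (lags up to `lag_max`, pairs
#' restricted to the same epoch), converted to power spectra, and read out at
#' the session's preferred lick frequency, i.e. the peak of the lick
#' autocorrelogram spectrum in 3-12 Hz. Powers are reported relative to the
#' mean spectral power in 0.5-25 Hz so that the two epochs are comparable.
#'
#' @param ss_times simple-spike times (s).
#' @param licks a [lick_train()].
#' @param bouts optional [segment_bouts()] table.
#' @param lag_max autocorrelogram half-width (s), default 2.
#' @param bin autocorrelogram bin (s), default 0.01.
#' @return list of class `power_result`: `freq_grid`, `power_in_bout`,
#'   `power_out_bout` (full spectra), `preferred_lick_freq`,
#'   `power_at_pref_in`, `power_at_pref_out`, `flagged`.
#' @export
autocorr_power <- function(ss_times, licks, bouts = NULL, lag_max = 2,
                           bin = 0.01) {
  if (is.null(bouts)) bouts <- segment_bouts(licks)
  ep <- bout_epochs(bouts, licks$session_duration)
  assign_epoch <- function(t, epochs) {
    if (!nrow(epochs)) return(rep(NA_integer_, length(t)))
    i <- findInterval(t, epochs[, 1])
    ok <- i >= 1
    ok[ok] <- t[ok] <= epochs[i[ok], 2]
    ifelse(ok, i, NA_integer_)
  }
  spectrum_of <- function(ev, grp) {
    keep <- !is.na(grp)
    ev <- ev[keep]; grp <- grp[keep]
    cg <- warped_correlogram(ev, grp, ev, grp, lag_max, bin,
                             exclude_self = TRUE)
    if (length(ev)) cg <- cg / (length(ev) * bin)   # conditional rate, Hz
    n <- length(cg)
    p <- Mod(stats::fft((cg - mean(cg)) * hann_window(n)))^2
    f <- (seq_len(n) - 1) / (n * bin)
    list(f = f, p = p, n_events = length(ev))
  }
  grp_in <- assign_epoch(ss_times, ep$in_bout)
  grp_out <- assign_epoch(ss_times, ep$out_bout)
  sp_in <- spectrum_of(ss_times, grp_in)
  sp_out <- spectrum_of(ss_times, grp_out)
  lick_grp <- assign_epoch(licks$detect_times, ep$in_bout)
  sp_lick <- spectrum_of(licks$detect_times, lick_grp)
  f <- sp_lick$f
  in_band <- f >= 3 & f <= 12
  pref <- if (any(in_band)) f[in_band][which.max(sp_lick$p[in_band])] else NA_real_
  rel_power <- function(sp, f0) {
    norm_band <- sp$f >= 0.5 & sp$f <= 25
    denom <- mean(sp$p[norm_band])
    if (!is.finite(denom) || denom <= 0 || is.na(f0)) return(NA_real_)
    sp$p[which.min(abs(sp$f - f0))] / denom
  }
  total_in <- sum(ep$in_bout[, 2] - ep$in_bout[, 1])
  total_out <- sum(ep$out_bout[, 2] - ep$out_bout[, 1])
  structure(list(freq_grid = sp_in$f,
                 power_in_bout = sp_in$p, power_out_bout = sp_out$p,
                 preferred_lick_freq = pref,
                 power_at_pref_in = rel_power(sp_in, pref),
                 power_at_pref_out = rel_power(sp_out, pref),
                 flagged = total_in < 2 || total_out < 2),
            class = "power_result")
}

#' Reduce per-cell values on the 8 x 4 electrode grid to a 7 x 3 matrix
#'
#' Each entry of the output is the mean of the available values in the
#' corresponding 2 x 2 neighbourhood of the input grid, which smooths
#' unequal sampling across electrodes. Neighbourhoods with no data give `NA`.
#'
#' @param values numeric per-cell values.
#' @param grid_row,grid_col integer electrode coordinates (rows 1-8, cols 1-4).
#' @return a 7 x 3 numeric matrix.
#' @export
grid_summary <- function(values, grid_row, grid_col) {
  stopifnot(length(values) == length(grid_row),
            length(values) == length(grid_col))
  if (length(grid_row) && (any(grid_row < 1 | grid_row > 8) ||
                           any(grid_col < 1 | grid_col > 4))) {
    stop("grid coordinates out of the 8 x 4 range")
  }
  g <- matrix(NA_real_, 8, 4)
  cnt <- matrix(0L, 8, 4)
  for (i in seq_along(values)) {
    r <- grid_row[i]; c <- grid_col[i]
    if (is.na(values[i])) next
    g[r, c] <- if (cnt[r, c]) (g[r, c] * cnt[r, c] + values[i]) / (cnt[r, c] + 1) else values[i]
    cnt[r, c] <- cnt[r, c] + 1L
  }
  out <- matrix(NA_real_, 7, 3)
  for (i in 1:7) for (j in 1:3) {
    block <- g[i:(i + 1), j:(j + 1)]
    if (any(!is.na(block))) out[i, j] <- mean(block, na.rm = TRUE)
  }
  out
}
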