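# Seeded generative model of a full session with known ground truth.
#
# The generator emulates the statistical structure of the recordings:
# ~6 Hz licking organised in bouts (intra-bout intervals < 500 ms), simple
# spikes phase-locked to the lick cycle via a von Mises rate profile, sparse
# (~1 Hz) complex spikes with multiplicative rate bumps at bout transitions
# and after lick-port movements, the >= 8 ms simple-spike pause after every
# complex spike, and endpoint / perturbation / optogenetic effects on the
# tongue coordinates. Every latent parameter is returned as ground truth so
# that each analysis stage can be tested by parameter recovery.

#' Behavioural generator parameters
#'
#' Defaults emulate head-fixed mice licking spontaneously at just above 6 Hz
#' in bouts of geometric size, with a ~4 mm tongue protrusion.
#'
#' @param lick_rate_mean intra-bout lick rate (Hz); 6.25 Hz corresponds to a
#'   160 ms inter-lick interval.
#' @param ili_cv coefficient of variation of intra-bout inter-lick intervals.
#' @param bout_size_mean mean bout size in licks (geometric distribution).
#' @param interbout_mean mean inter-bout gap (s); gaps are 0.5 s plus an
#'   exponential so that every inter-bout gap exceeds the bout threshold.
#' @param endpoint_mean_x,endpoint_mean_y mean tongue endpoint (mm).
#' @param endpoint_sd_x,endpoint_sd_y per-lick endpoint scatter (mm).
#' @param maxprot_delay detection-to-maximal-protrusion delay (s).
#' @param follow_gain length-3 fraction of a port displacement tracked by
#'   the 1st/2nd/3rd lick after the movement.
#' @param opto_bend ipsiversive endpoint shift of the first lick after
#'   optogenetic stimulation (mm; sign follows the stimulated side).
#' @param opto_shorten reduction of protrusion extension of that lick (mm).
#' @export
behaviour_spec <- function(lick_rate_mean = 6.25, ili_cv = 0.1,
                           bout_size_mean = 8, interbout_mean = 2.0,
                           endpoint_mean_x = 0, endpoint_mean_y = 4.2,
                           endpoint_sd_x = 0.5, endpoint_sd_y = 0.7,
                           maxprot_delay = 0.016,
                           follow_gain = c(0.5, 1.0, 1.0),
                           opto_bend = 0.5, opto_shorten = 0.3) {
  stopifnot(lick_rate_mean > 0, ili_cv >= 0, bout_size_mean >= 1,
            interbout_mean > 0.5, endpoint_sd_x >= 0, endpoint_sd_y >= 0,
            maxprot_delay >= 0, length(follow_gain) == 3,
            all(follow_gain >= 0 & follow_gain <= 1))
  structure(as.list(environment()), class = "behaviour_spec")
}

#' Single-cell generator parameters
#'
#' Simple spikes follow an inhomogeneous Poisson process whose rate inside
#' lick cycles is `ss_base_rate * exp(kappa * cos(phase - pref)) / I0(kappa)`
#' (mean rate preserved) and `ss_base_rate` outside bouts. Complex spikes are
#' a sparse Poisson process with multiplicative rate bumps of 0.3 s duration
#' at bout transitions and after lick-port movements, and optional von Mises
#' lick-phase locking. After every complex spike all simple spikes within
#' `cs_pause` are deleted, enforcing the pause criterion by construction.
#'
#' @param ss_base_rate simple-spike base rate (Hz).
#' @param ss_phase_pref preferred lick phase of simple spikes (rad).
#' @param ss_kappa von Mises concentration of simple-spike locking
#'   (0 = none; capped at 20).
#' @param ss_bout_gain multiplicative in-bout simple-spike rate gain: the
#'   rate inside lick cycles is scaled by `1 + ss_bout_gain`.
#' @param ss_endpoint_gain_x lateral kinematic coupling (per mm): the SS
#'   rate inside a lick's cycle is scaled by `1 + gain * endpoint_x` of that
#'   lick (clamped below at 0.05), so positive gains make ipsiversive licks
#'   coincide with stronger firing.
#' @param cs_base_rate complex-spike base rate (Hz).
#' @param cs_bout_start_gain,cs_bout_end_gain multiplicative CS rate bumps
#'   in the 0.3 s window centred on the first/last lick of each bout
#'   (0 = no bump; gain g makes the rate `(1+g) * cs_base_rate`).
#' @param cs_move_gain_right,cs_move_gain_centre CS bumps in the 0.3 s after
#'   rightward / centreward lick-port movements.
#' @param cs_pause simple-spike pause after each complex spike (s, >= 0.008).
#' @param cs_lick_phase_pref,cs_lick_kappa complex-spike phase locking.
#' @export
cell_spec <- function(ss_base_rate = 70, ss_phase_pref = pi, ss_kappa = 2,
                      ss_bout_gain = 0, ss_endpoint_gain_x = 0,
                      cs_base_rate = 1, cs_bout_start_gain = 0,
                      cs_bout_end_gain = 0, cs_move_gain_right = 0,
                      cs_move_gain_centre = 0, cs_pause = 0.008,
                      cs_lick_phase_pref = 0, cs_lick_kappa = 0) {
  stopifnot(ss_base_rate >= 0, cs_base_rate >= 0, ss_kappa >= 0,
            cs_lick_kappa >= 0, cs_pause >= 0.008, ss_bout_gain >= 0,
            cs_bout_start_gain >= 0, cs_bout_end_gain >= 0,
            cs_move_gain_right >= 0, cs_move_gain_centre >= 0)
  ss_kappa <- min(ss_kappa, 20)      # rate overflow guard
  cs_lick_kappa <- min(cs_lick_kappa, 20)
  structure(as.list(environment()), class = "cell_spec")
}

# independent substream seeds derived from one session seed; drawing them as
# a sequential without-replacement sample makes the first k seeds invariant
# to how many are requested, so adding a cell never perturbs behaviour
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic lick train
#'
#' Bouts of geometric size with i.i.d. Gamma intra-bout intervals (given mean
#' and CV, resampled in the vanishingly rare case an interval would reach the
#' 0.5 s bout threshold), inter-bout gaps of 0.5 s plus an exponential,
#' 2-D Gaussian endpoints about the current port position, and
#' maximal-protrusion times at detection plus the protrusion delay.
#'
#' @param spec a [behaviour_spec()].
#' @param duration session length (s).
#' @param seed integer RNG seed.
#' @return a [lick_train()] with an integer attribute `bout_id` giving the
#'   generated bout partition (ground truth for [segment_bouts()]).
#' @export
generate_licks <- function(spec, duration, seed) {
  stopifnot(inherits(spec, "behaviour_spec"))
  if (duration <= 0) stop("duration must be positive")
  set.seed(seed)
  mean_ili <- 1 / spec$lick_rate_mean
  draw_ili <- function(n) {
    if (spec$ili_cv < 1e-9) return(rep(mean_ili, n))
    shape <- 1 / spec$ili_cv^2
    x <- stats::rgamma(n, shape = shape, scale = mean_ili / shape)
    while (any(x >= 0.499)) {        # keep intra-bout gaps below threshold
      bad <- x >= 0.499
      x[bad] <- stats::rgamma(sum(bad), shape = shape, scale = mean_ili / shape)
    }
    x
  }
  t <- numeric(0); bout_id <- integer(0)
  cur <- stats::runif(1, 0.2, 0.7)   # first bout start
  b <- 0L
  repeat {
    size <- 1L + stats::rgeom(1, 1 / spec$bout_size_mean)
    ilis <- if (size > 1) draw_ili(size - 1L) else numeric(0)
    times <- cur + c(0, cumsum(ilis))
    times <- times[times <= duration]
    if (!length(times)) break
    b <- b + 1L
    t <- c(t, times)
    bout_id <- c(bout_id, rep(b, length(times)))
    gap <- 0.5 + stats::rexp(1, rate = 1 / (spec$interbout_mean - 0.5))
    cur <- t[length(t)] + gap
    if (cur > duration) break
  }
  n <- length(t)
  if (!n) stop("duration too short to place any lick")
  lt <- lick_train(
    t, session_duration = duration,
    endpoint_x = stats::rnorm(n, spec$endpoint_mean_x, spec$endpoint_sd_x),
    endpoint_y = stats::rnorm(n, spec$endpoint_mean_y, spec$endpoint_sd_y),
    max_protrusion_times = t + spec$maxprot_delay)
  attr(lt, "bout_id") <- bout_id
  lt
}

# inhomogeneous Poisson times on [0, duration] by thinning under a constant
# envelope; rate_fn must be vectorised and bounded by rate_max
poisson_thinning <- function(rate_fn, rate_max, duration) {
  if (rate_max <= 0) return(numeric(0))
  n <- stats::rpois(1, rate_max * duration)
  # unique(): R's RNG has ~2^32 granularity, so exact ties occur at this n
  cand <- unique(sort(stats::runif(n, 0, duration)))
  keep <- stats::runif(length(cand)) < rate_fn(cand) / rate_max
  cand[keep]
}

von_mises_factor <- function(phase, pref, kappa) {
  out <- rep(1, length(phase))
  inb <- !is.na(phase)
  if (kappa > 0) {
    out[inb] <- exp(kappa * cos(phase[inb] - pref)) / besselI(kappa, 0)
  }
  out
}

# multiplicative bump profile: product over windows of (1 + gain)
bump_factor <- function(t, windows, gains) {
  f <- rep(1, length(t))
  for (i in seq_along(gains)) {
    if (gains[i] <= 0 || !nrow(windows[[i]])) next
    w <- windows[[i]]
    hit <- rep(FALSE, length(t))
    for (r in seq_len(nrow(w))) hit <- hit | (t >= w[r, 1] & t < w[r, 2])
    f[hit] <- f[hit] * (1 + gains[i])
  }
  f
}

#' Generate one synthetic cell for a given lick train
#'
#' @param spec a [cell_spec()].
#' @param licks a [lick_train()] (normally from [generate_licks()]).
#' @param seed integer RNG seed.
#' @param cell_id identifier.
#' @param port_events optional data frame with columns `time, direction`
#'   (`"rightward"`/`"centreward"`) of lick-port movement events driving the
#'   CS movement bumps.
#' @param grid_row,grid_col,region_tag electrode metadata.
#' @return a [cell_recording()].
#' @export
generate_cell <- function(spec, licks, seed, cell_id = "cell",
                          port_events = NULL, grid_row = 1, grid_col = 1,
                          region_tag = "medial") {
  stopifnot(inherits(spec, "cell_spec"), inherits(licks, "lick_train"))
  set.seed(seed)
  duration <- licks$session_duration
  pm <- build_phase_map(licks)
  bouts <- segment_bouts(licks)

  # per-cycle endpoint coupling factor (cycle row -> lick -> endpoint x)
  ep_factor <- rep(1, max(nrow(pm$cycles), 1))
  if (spec$ss_endpoint_gain_x != 0 && !is.null(licks$endpoint_x) &&
      nrow(pm$cycles)) {
    x <- licks$endpoint_x[pm$cycles$lick_index]
    ep_factor <- pmax(1 + spec$ss_endpoint_gain_x * ifelse(is.na(x), 0, x),
                      0.05)
  }
  ss_rate <- function(t) {
    ph <- phase_at(pm, t)
    inb <- !is.na(ph$phase)
    f <- rep(1, length(t))
    f[inb] <- (1 + spec$ss_bout_gain) * ep_factor[ph$cycle[inb]] *
      von_mises_factor(ph$phase[inb], spec$ss_phase_pref, spec$ss_kappa)
    spec$ss_base_rate * f
  }
  ss_max <- spec$ss_base_rate * (1 + spec$ss_bout_gain) * max(ep_factor) *
    (if (spec$ss_kappa > 0) exp(spec$ss_kappa) / besselI(spec$ss_kappa, 0) else 1)
  ss <- poisson_thinning(ss_rate, ss_max, duration)

  half <- 0.15
  win <- function(centres, lo, hi) {
    if (!length(centres)) return(matrix(numeric(0), 0, 2))
    cbind(centres + lo, centres + hi)
  }
  move_r <- move_c <- numeric(0)
  if (!is.null(port_events) && nrow(port_events)) {
    move_r <- port_events$time[port_events$direction == "rightward"]
    move_c <- port_events$time[port_events$direction == "centreward"]
  }
  windows <- list(win(bouts$start_time, -half, half),
                  win(bouts$end_time, -half, half),
                  win(move_r, 0, 0.3), win(move_c, 0, 0.3))
  gains <- c(spec$cs_bout_start_gain, spec$cs_bout_end_gain,
             spec$cs_move_gain_right, spec$cs_move_gain_centre)
  cs_rate <- function(t) {
    ph <- phase_at(pm, t)$phase
    spec$cs_base_rate *
      von_mises_factor(ph, spec$cs_lick_phase_pref, spec$cs_lick_kappa) *
      bump_factor(t, windows, gains)
  }
  vm_max <- if (spec$cs_lick_kappa > 0)
    exp(spec$cs_lick_kappa) / besselI(spec$cs_lick_kappa, 0) else 1
  cs_max <- spec$cs_base_rate * vm_max * prod(1 + gains[gains > 0])
  cs <- poisson_thinning(cs_rate, cs_max, duration)

  # climbing-fibre pause: drop SS within cs_pause after each CS
  if (length(cs) && length(ss)) {
    prev_cs <- findInterval(ss, cs)
    hit <- prev_cs >= 1 & (ss - cs[pmax(prev_cs, 1)]) < spec$cs_pause
    ss <- ss[!hit]
  }
  cell_recording(cell_id, ss, cs, grid_row = grid_row, grid_col = grid_col,
                 region_tag = region_tag)
}

# closed-loop port movement schedule: each lick at a centred, available port
# triggers a 3 mm rightward movement with probability 1/2, onset 40 ms after
# detection, return after 750 ms, and a further 750 ms refractory period
schedule_port_trials <- function(licks, n_trials, seed,
                                 p_trigger = 0.5, onset_delay = 0.040,
                                 travel = 0.050, hold = 0.750,
                                 refractory = 0.750, displacement = 3.0) {
  set.seed(seed)
  t <- licks$detect_times
  trig <- integer(0); onsets <- numeric(0)
  next_avail <- -Inf
  eligible <- 0L
  for (i in seq_along(t)) {
    if (t[i] < next_avail) next
    eligible <- eligible + 1L
    if (length(trig) >= n_trials) next
    if (stats::runif(1) < p_trigger) {
      trig <- c(trig, i)
      on <- t[i] + onset_delay
      onsets <- c(onsets, on)
      next_avail <- on + hold + refractory
    }
  }
  if (length(trig) < n_trials) {
    stop("over-subscribed trial plan: requested ", n_trials,
         " port trials but only ", length(trig),
         " could be triggered (", eligible, " eligible licks)")
  }
  data.frame(trigger_lick_idx = trig, move_onset_s = onsets,
             direction = "rightward", displacement_mm = displacement,
             travel_s = travel, return_s = onsets + hold)
}

# behavioural adaptation: after each port position change the k-th following
# lick aims at old + gain_k * (new - old); from the 4th lick, or after the
# 750 ms the port holds its position, tracking is complete
apply_follow_gain <- function(licks, port_events, follow_gain, displacement,
                              settle = 0.750) {
  x <- licks$endpoint_x
  t <- licks$detect_times
  aim <- rep(0, length(t))
  pos <- 0
  if (nrow(port_events)) {
    ev <- port_events[order(port_events$time), ]
    for (r in seq_len(nrow(ev))) {
      new_pos <- if (ev$direction[r] == "rightward") displacement else 0
      after <- which(t > ev$time[r])   # later events overwrite these aims
      aim[after] <- new_pos
      lead <- after[t[after] <= ev$time[r] + settle]
      lead <- lead[seq_len(min(3, length(lead)))]
      aim[lead] <- pos + follow_gain[seq_along(lead)] * (new_pos - pos)
      pos <- new_pos
    }
  }
  licks$endpoint_x <- x + aim
  attr(licks, "aim_x") <- aim
  licks
}

# optogenetic stimulation schedule + behavioural effect (bend of the first
# lick after pulse onset toward the stimulated side, shortened protrusion)
schedule_opto_trials <- function(licks, plan, seed, refractory = 1.0) {
  set.seed(seed)
  t <- licks$detect_times
  rows <- list(); next_avail <- -Inf; k <- 0L
  arms <- plan$arms %||% data.frame(onset_offset_s = 0.010, duration_s = 0.160,
                                    fibre = "right_medial")
  for (i in seq_along(t)) {
    if (t[i] < next_avail || k >= plan$n_trials) next
    if (stats::runif(1) < (plan$p_trigger %||% 0.5)) {
      k <- k + 1L
      arm <- arms[1L + (k - 1L) %% nrow(arms), ]
      rows[[k]] <- data.frame(trigger_lick_idx = i,
                              onset_offset_s = arm$onset_offset_s,
                              duration_s = arm$duration_s, fibre = arm$fibre)
      next_avail <- t[i] + refractory
    }
  }
  if (k < plan$n_trials) {
    stop("over-subscribed trial plan: requested ", plan$n_trials,
         " opto trials but only ", k, " could be placed")
  }
  do.call(rbind, rows)
}

apply_opto_effects <- function(licks, opto_trials, bend, shorten) {
  t <- licks$detect_times
  affected <- integer(0)
  for (r in seq_len(nrow(opto_trials))) {
    onset <- t[opto_trials$trigger_lick_idx[r]] + opto_trials$onset_offset_s[r]
    j <- which(t > onset)[1]
    if (is.na(j)) next
    sgn <- switch(as.character(opto_trials$fibre[r]),
                  right_medial = 1, lateral = 1, left_medial = -1, both = 0, 1)
    licks$endpoint_x[j] <- licks$endpoint_x[j] + sgn * bend
    licks$endpoint_y[j] <- licks$endpoint_y[j] - shorten
    affected <- c(affected, j)
  }
  attr(licks, "opto_affected") <- affected
  licks
}

#' Generate a complete synthetic session with ground truth
#'
#' Composes [generate_licks()], the closed-loop lick-port movement protocol,
#' an optional optogenetic stimulation plan and [generate_cell()] for each
#' cell spec. One session seed is split into independent substreams
#' (behaviour, port schedule, opto schedule, one per cell) so that adding a
#' cell never perturbs the behaviour stream.
#'
#' @param behaviour a [behaviour_spec()].
#' @param cell_specs list of [cell_spec()] objects (optionally named).
#' @param duration session length (s).
#' @param seed integer session seed.
#' @param n_port_trials number of rightward lick-port movements to schedule.
#' @param opto_plan optional list with `n_trials`, optional `p_trigger`, and
#'   optional `arms` data frame (`onset_offset_s, duration_s, fibre`).
#' @return list with elements `session` (a [session()]) and `truth` (latent
#'   parameters: specs, bout partition, endpoint aims, affected licks, seeds).
#' @export
generate_session <- function(behaviour, cell_specs = list(), duration = 600,
                             seed = 1, n_port_trials = 0, opto_plan = NULL) {
  stopifnot(inherits(behaviour, "behaviour_spec"))
  seeds <- substream_seeds(seed, 3 + length(cell_specs))
  licks <- generate_licks(behaviour, duration, seeds[1])
  bout_id <- attr(licks, "bout_id")

  port_trials <- NULL
  port_events <- data.frame(time = numeric(), direction = character())
  if (n_port_trials > 0) {
    port_trials <- schedule_port_trials(licks, n_port_trials, seeds[2])
    port_events <- rbind(
      data.frame(time = port_trials$move_onset_s, direction = "rightward"),
      data.frame(time = port_trials$return_s, direction = "centreward"))
    port_events <- port_events[order(port_events$time), ]
    licks <- apply_follow_gain(licks, port_events, behaviour$follow_gain,
                               port_trials$displacement_mm[1])
  }
  opto_trials <- NULL
  if (!is.null(opto_plan) && (opto_plan$n_trials %||% 0) > 0) {
    opto_trials <- schedule_opto_trials(licks, opto_plan, seeds[3])
    licks <- apply_opto_effects(licks, opto_trials, behaviour$opto_bend,
                                behaviour$opto_shorten)
  }
  ids <- names(cell_specs)
  if (is.null(ids)) ids <- sprintf("cell%02d", seq_along(cell_specs))
  cells <- vector("list", length(cell_specs))
  for (i in seq_along(cell_specs)) {
    cells[[i]] <- generate_cell(
      cell_specs[[i]], licks, seeds[3 + i], cell_id = ids[i],
      port_events = port_events,
      grid_row = 1L + (i - 1L) %% 8L, grid_col = 1L + (i - 1L) %/% 8L %% 4L)
  }
  sess <- session(licks, cells, port_trials = port_trials,
                  opto_trials = opto_trials,
                  metadata = list(seed = seed, duration = duration))
  truth <- list(behaviour = behaviour, cell_specs = stats::setNames(cell_specs, ids),
                bout_id = bout_id, aim_x = attr(licks, "aim_x"),
                opto_affected = attr(licks, "opto_affected"),
                port_events = port_events, seeds = seeds)
  list(session = sess, truth = truth)
}
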