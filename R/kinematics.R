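# Tongue-endpoint ("rosette") analysis: per-session tertile grid over the
# endpoints at maximal protrusion, simple-spike Z maps in the two
# pre-protrusion windows, and the ipsiversive/contraversive comparison.
#
# "Ipsiversive" is positive x (toward the animal's right, ipsilateral to
# right-hemisphere recordings); set `flip_x = TRUE` for left-hemisphere data.

#' Build the per-session endpoint rosette
#'
#' The endpoint distribution is divided into tertiles independently on the
#' lateral (x) and rostro-caudal (y) axis, using that session's empirical
#' 1/3 and 2/3 quantiles so the analysis adapts to each animal's individual
#' bias. Values equal to an edge go to the upper tertile.
#'
#' @param licks a [lick_train()] with endpoint coordinates.
#' @return object of class `rosette`: `x_edges`, `y_edges`, `zone_col`
#'   (x tertile 1-3), `zone_row` (y tertile 1-3) and `zone` (1-9,
#'   `(row-1)*3 + col`) per lick; licks with missing endpoints get `NA`.
#' @export
build_rosette <- function(licks) {
  x <- licks$endpoint_x; y <- licks$endpoint_y
  if (is.null(x) || is.null(y)) stop("rosette requires endpoint coordinates")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 9) stop("rosette requires at least 9 licks with endpoints")
  x_edges <- stats::quantile(x[ok], c(1, 2) / 3, names = FALSE, type = 7)
  y_edges <- stats::quantile(y[ok], c(1, 2) / 3, names = FALSE, type = 7)
  tertile <- function(v, e) 1L + (v >= e[1]) + (v >= e[2])
  col <- ifelse(ok, tertile(x, x_edges), NA_integer_)
  row <- ifelse(ok, tertile(y, y_edges), NA_integer_)
  structure(list(x_edges = x_edges, y_edges = y_edges,
                 zone_col = col, zone_row = row,
                 zone = (row - 1L) * 3L + col, n = sum(ok)),
            class = "rosette")
}

#' @export
print.rosette <- function(x, ...) {
  cat(sprintf("<rosette> %d licks; x edges %.2f/%.2f mm, y edges %.2f/%.2f mm\n",
              x$n, x$x_edges[1], x$x_edges[2], x$y_edges[1], x$y_edges[2]))
  invisible(x)
}

#' Simple-spike Z maps over the rosette zones
#'
#' For each lick, the simple-spike rate in each pre-protrusion window
#' (early: -150 to -75 ms, late: -75 to 0 ms relative to maximal protrusion)
#' is Z-scored against the across-lick distribution of baseline rates
#' (-1000 to -250 ms before detection) and averaged per rosette zone.
#' A finely binned (10 ms) per-lick Z matrix over the late 150 ms is also
#' returned for peak statistics.
#'
#' @param cell a [cell_recording()].
#' @param licks a [lick_train()] with endpoints.
#' @param rosette a [build_rosette()]; built on the fly when `NULL`.
#' @param windows named list of windows (s) relative to maximal protrusion.
#' @param baseline per-lick baseline window (s) relative to detection.
#' @return object of class `zone_map`: one 3 x 3 matrix per window (rows =
#'   y tertiles, columns = x tertiles), marginal means, per-lick values and
#'   a per-lick binned-Z matrix spanning -150..0 ms in 10 ms bins.
#' @export
zone_ss_map <- function(cell, licks, rosette = NULL,
                        windows = list(early = c(-0.150, -0.075),
                                       late = c(-0.075, 0)),
                        baseline = c(-1.0, -0.25)) {
  if (is.null(rosette)) rosette <- build_rosette(licks)
  t_det <- licks$detect_times
  t_max <- max_protrusion(licks)
  base <- per_lick_baseline(cell$ss_times, t_det, baseline)
  mu <- mean(base); sdv <- stats::sd(base)
  zs <- lapply(windows, function(w) {
    r <- window_rates(cell$ss_times, t_max, w)
    if (!is.finite(sdv) || sdv == 0) rep(NA_real_, length(r)) else (r - mu) / sdv
  })
  bin_edges <- seq(-0.150, 0, by = 0.010)
  binned <- sapply(seq_len(length(bin_edges) - 1), function(b) {
    r <- window_rates(cell$ss_times, t_max, bin_edges[b + (0:1)])
    if (!is.finite(sdv) || sdv == 0) rep(NA_real_, length(r)) else (r - mu) / sdv
  })
  maps <- lapply(zs, function(z) {
    m <- matrix(NA_real_, 3, 3)
    for (r in 1:3) for (c in 1:3) {
      sel <- !is.na(rosette$zone_row) & rosette$zone_row == r &
        rosette$zone_col == c
      if (any(sel)) m[r, c] <- mean(z[sel], na.rm = TRUE)
    }
    m
  })
  per_lick <- data.frame(lick = seq_along(t_det),
                         zone_row = rosette$zone_row,
                         zone_col = rosette$zone_col)
  for (nm in names(zs)) per_lick[[paste0("z_", nm)]] <- zs[[nm]]
  structure(list(maps = maps, windows = windows, rosette = rosette,
                 per_lick = per_lick, binned_z = binned,
                 binned_edges = bin_edges,
                 marginal_x = lapply(maps, colMeans, na.rm = TRUE),
                 marginal_y = lapply(maps, rowMeans, na.rm = TRUE),
                 zero_sd = !is.finite(sdv) || sdv == 0),
            class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat("<zone_map> windows:", paste(names(x$maps), collapse = ", "), "\n")
  for (nm in names(x$maps)) {
    cat(nm, ":\n")
    print(round(x$maps[[nm]], 2))
  }
  invisible(x)
}

#' Ipsiversive versus contraversive simple-spike firing
#'
#' Contrasts the late-window (75-0 ms pre-protrusion) simple-spike Z between
#' licks bending into the outer lateral tertiles: ipsiversive (positive x,
#' column 3) versus contraversive (column 1). Returns the per-cell group
#' means and the peaks of the group-mean binned Z, ready for population
#' testing.
#'
#' @param zone_map a [zone_ss_map()] result.
#' @param flip_x set for left-hemisphere recordings (ipsiversive = negative x).
#' @return list of class `lateral_result`: `mean_ipsi`, `mean_contra`,
#'   `peak_ipsi`, `peak_contra`, `n_ipsi`, `n_contra`.
#' @export
lateral_comparison <- function(zone_map, flip_x = FALSE) {
  pl <- zone_map$per_lick
  ipsi_col <- if (flip_x) 1L else 3L
  contra_col <- if (flip_x) 3L else 1L
  sel_i <- !is.na(pl$zone_col) & pl$zone_col == ipsi_col
  sel_c <- !is.na(pl$zone_col) & pl$zone_col == contra_col
  if (!any(sel_i) || !any(sel_c)) stop("a lateral tertile is unpopulated")
  late <- zone_map$windows$late %||% c(-0.075, 0)
  centres <- (zone_map$binned_edges[-1] +
                zone_map$binned_edges[-length(zone_map$binned_edges)]) / 2
  late_bins <- centres > late[1] & centres < late[2]
  peak_of <- function(sel) {
    m <- colMeans(zone_map$binned_z[sel, , drop = FALSE], na.rm = TRUE)
    max(m[late_bins])
  }
  structure(list(mean_ipsi = mean(pl$z_late[sel_i], na.rm = TRUE),
                 mean_contra = mean(pl$z_late[sel_c], na.rm = TRUE),
                 peak_ipsi = peak_of(sel_i), peak_contra = peak_of(sel_c),
                 n_ipsi = sum(sel_i), n_contra = sum(sel_c)),
            class = "lateral_result")
}

#' @export
print.lateral_result <- function(x, ...) {
  cat(sprintf(
    "<lateral> mean Z ipsi %.2f vs contra %.2f; peak %.2f vs %.2f (n %d/%d)\n",
    x$mean_ipsi, x$mean_contra, x$peak_ipsi, x$peak_contra,
    x$n_ipsi, x$n_contra))
  invisible(x)
}
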