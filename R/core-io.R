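# Domain containers and event-table I/O.
#
# All times are seconds from session start, all coordinates millimetres.
# x is lateral (positive = animal's right, ipsilateral to right-hemisphere
# recordings), y is the protrusion axis (positive = rostral), origin at the
# resting spout position.

#' Lick train
#'
#' Ordered lick detection times with optional tongue-endpoint coordinates and
#' maximal-protrusion times. This is the behavioural clock every other
#' analysis is aligned to.
#'
#' When `max_protrusion_times` are not recorded they are derived as
#' `detect_times + 0.016` s, the average sensor-to-maximal-protrusion delay
#' observed with video tracking.
#'
#' @param detect_times numeric, strictly increasing lick detection times (s).
#' @param session_duration session length (s); defaults to the last lick.
#' @param endpoint_x,endpoint_y optional per-lick tongue endpoint at maximal
#'   protrusion (mm); `NA` marks licks without video coverage.
#' @param max_protrusion_times optional per-lick time of maximal protrusion (s).
#' @return an object of class `lick_train`.
#' @export
lick_train <- function(detect_times, session_duration = NULL,
                       endpoint_x = NULL, endpoint_y = NULL,
                       max_protrusion_times = NULL) {
  detect_times <- as.numeric(detect_times)
  n <- length(detect_times)
  if (n > 1) {
    bad <- which(diff(detect_times) <= 0)
    if (length(bad)) {
      stop("lick detect_times not strictly increasing at index ", bad[1] + 1)
    }
  }
  if (is.null(session_duration)) {
    session_duration <- if (n) detect_times[n] else 0
  }
  if (n && (detect_times[1] < 0 || detect_times[n] > session_duration)) {
    stop("lick times must lie in [0, session_duration]")
  }
  for (nm in c("endpoint_x", "endpoint_y", "max_protrusion_times")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n) {
      stop(nm, " must have one entry per lick (", n, "), got ", length(v))
    }
  }
  structure(
    list(detect_times = detect_times,
         endpoint_x = if (is.null(endpoint_x)) NULL else as.numeric(endpoint_x),
         endpoint_y = if (is.null(endpoint_y)) NULL else as.numeric(endpoint_y),
         max_protrusion_times = if (is.null(max_protrusion_times)) NULL
                                else as.numeric(max_protrusion_times),
         session_duration = as.numeric(session_duration)),
    class = "lick_train")
}

#' @export
print.lick_train <- function(x, ...) {
  cat(sprintf("<lick_train> %d licks over %.1f s (%s endpoints)\n",
              length(x$detect_times), x$session_duration,
              if (is.null(x$endpoint_x)) "no" else "with"))
  invisible(x)
}

#' Number of licks in a lick train
#' @param licks a [lick_train()].
#' @export
n_licks <- function(licks) length(licks$detect_times)

#' Maximal-protrusion times of a lick train
#'
#' Returns the recorded times, or `detect_times + delay` when they were not
#' recorded.
#'
#' @param licks a [lick_train()].
#' @param delay sensor-to-maximal-protrusion delay used when no recorded
#'   times are available (s).
#' @export
max_protrusion <- function(licks, delay = 0.016) {
  if (!is.null(licks$max_protrusion_times)) return(licks$max_protrusion_times)
  licks$detect_times + delay
}

#' Single-cell recording
#'
#' Simple-spike and complex-spike time lists for one Purkinje cell, together
#' with its position on the 8 x 4 electrode entry grid.
#'
#' @param cell_id identifier string.
#' @param ss_times,cs_times strictly increasing spike times (s).
#' @param grid_row integer 1-8, @param grid_col integer 1-4 electrode entry
#'   coordinates.
#' @param region_tag `"medial"` or `"lateral"`.
#' @return an object of class `cell_recording`.
#' @export
cell_recording <- function(cell_id, ss_times, cs_times,
                           grid_row = NA_integer_, grid_col = NA_integer_,
                           region_tag = c("medial", "lateral")) {
  region_tag <- match.arg(region_tag)
  ss_times <- as.numeric(ss_times)
  cs_times <- as.numeric(cs_times)
  for (nm in c("ss_times", "cs_times")) {
    v <- get(nm)
    if (length(v) > 1 && any(diff(v) <= 0)) {
      stop(nm, " not strictly increasing at index ",
           which(diff(v) <= 0)[1] + 1, " for cell ", cell_id)
    }
  }
  if (!is.na(grid_row) && (grid_row < 1 || grid_row > 8)) {
    stop("grid_row out of 1-8 for cell ", cell_id)
  }
  if (!is.na(grid_col) && (grid_col < 1 || grid_col > 4)) {
    stop("grid_col out of 1-4 for cell ", cell_id)
  }
  structure(
    list(cell_id = as.character(cell_id), ss_times = ss_times,
         cs_times = cs_times, grid_row = as.integer(grid_row),
         grid_col = as.integer(grid_col), region_tag = region_tag),
    class = "cell_recording")
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf("<cell_recording> %s: %d SS, %d CS, grid (%s,%s) %s\n",
              x$cell_id, length(x$ss_times), length(x$cs_times),
              x$grid_row, x$grid_col, x$region_tag))
  invisible(x)
}

#' Recording session
#'
#' Container holding one behavioural session: the lick train, zero or more
#' simultaneously recorded cells, and optional perturbation trial tables.
#'
#' @param licks a [lick_train()].
#' @param cells list of [cell_recording()] objects.
#' @param port_trials optional data frame of lick-port movement events (see
#'   [index_trial_licks()]).
#' @param opto_trials optional data frame of optogenetic stimulation trials.
#' @param metadata free-form named list.
#' @export
session <- function(licks, cells = list(), port_trials = NULL,
                    opto_trials = NULL, metadata = list()) {
  stopifnot(inherits(licks, "lick_train"))
  if (length(cells) && !all(vapply(cells, inherits, TRUE, "cell_recording"))) {
    stop("cells must be a list of cell_recording objects")
  }
  names(cells) <- vapply(cells, `[[`, "", "cell_id")
  structure(list(licks = licks, cells = cells, port_trials = port_trials,
                 opto_trials = opto_trials, metadata = metadata),
            class = "licklock_session")
}

#' @export
print.licklock_session <- function(x, ...) {
  cat(sprintf("<session> %d licks, %d cells, %d port trials, %d opto trials\n",
              n_licks(x$licks), length(x$cells),
              if (is.null(x$port_trials)) 0L else nrow(x$port_trials),
              if (is.null(x$opto_trials)) 0L else nrow(x$opto_trials)))
  invisible(x)
}

#' Segment a lick train into bouts
#'
#' A bout is a maximal run of licks whose consecutive inter-lick intervals
#' are all strictly below `max_gap`; a gap of exactly `max_gap` splits bouts.
#' Single-lick bouts are permitted.
#'
#' @param licks a [lick_train()] or a numeric vector of lick times (s).
#' @param max_gap bout-splitting gap threshold (s), default 0.5.
#' @return data frame with one row per bout: `first_lick_index`,
#'   `last_lick_index` (1-based), `start_time`, `end_time`, `n_licks`.
#' @examples
#' segment_bouts(c(0, 0.15, 0.30, 1.0, 1.15))
#' @export
segment_bouts <- function(licks, max_gap = 0.5) {
  t <- if (inherits(licks, "lick_train")) licks$detect_times else as.numeric(licks)
  if (!length(t)) {
    return(data.frame(first_lick_index = integer(), last_lick_index = integer(),
                      start_time = numeric(), end_time = numeric(),
                      n_licks = integer()))
  }
  if (length(t) > 1) {
    bad <- which(diff(t) <= 0)
    if (length(bad)) stop("lick times not strictly increasing at index ", bad[1] + 1)
  }
  id <- cumsum(c(TRUE, diff(t) >= max_gap))
  first <- match(unique(id), id)
  last <- c(first[-1] - 1L, length(t))
  data.frame(first_lick_index = first, last_lick_index = last,
             start_time = t[first], end_time = t[last],
             n_licks = last - first + 1L)
}

#' Time intervals covered by bouts and by inter-bout periods
#'
#' @param bouts output of [segment_bouts()].
#' @param session_duration session length (s).
#' @return list of two 2-column matrices `in_bout` and `out_bout`
#'   of (start, end) epochs.
#' @export
bout_epochs <- function(bouts, session_duration) {
  if (!nrow(bouts)) {
    return(list(in_bout = cbind(numeric(), numeric()),
                out_bout = cbind(0, session_duration)))
  }
  inb <- cbind(bouts$start_time, bouts$end_time)
  starts <- c(0, bouts$end_time)
  ends <- c(bouts$start_time, session_duration)
  keep <- ends > starts
  list(in_bout = inb, out_bout = cbind(starts[keep], ends[keep]))
}

#' Check a cell against the inclusion criteria
#'
#' A recording qualifies as a single Purkinje cell only if every complex
#' spike is followed by a pause of at least `pause` (default 8 ms) before
#' simple-spike firing resumes, and if it offers at least `min_trials`
#' analysable trials (licks, or perturbation trials when supplied).
#' Violations are reported, never raised.
#'
#' @param cell a [cell_recording()].
#' @param n_trials number of analysable trials available for this cell
#'   (e.g. number of licks or perturbation trials).
#' @param min_trials minimum trial count, default 20.
#' @param pause minimum CS-to-SS pause (s), default 0.008.
#' @return list of class `validity_report`: `pause_ok`, `offending_cs`
#'   (CS times violating the pause), `trials_ok`, `n_trials`, `pass`.
#' @export
validate_cell <- function(cell, n_trials = NA_integer_, min_trials = 20,
                          pause = 0.008) {
  ss <- cell$ss_times
  cs <- cell$cs_times
  offending <- numeric()
  if (length(cs) && length(ss)) {
    # index of first SS strictly after each CS; a gap < pause violates
    nxt <- findInterval(cs, ss) + 1L
    ok <- nxt <= length(ss)
    gap <- rep(Inf, length(cs))
    gap[ok] <- ss[nxt[ok]] - cs[ok]
    offending <- cs[gap < pause]
  }
  trials_ok <- if (is.na(n_trials)) NA else n_trials >= min_trials
  pass <- length(offending) == 0 && length(cs) >= 1 && isTRUE(trials_ok)
  structure(list(cell_id = cell$cell_id,
                 pause_ok = length(offending) == 0,
                 offending_cs = offending,
                 has_cs = length(cs) >= 1,
                 trials_ok = trials_ok, n_trials = n_trials,
                 min_trials = min_trials, pass = pass),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> %s: pause %s (%d offenders), trials %s (%s), %s\n",
              x$cell_id, if (x$pause_ok) "ok" else "FAIL",
              length(x$offending_cs),
              if (isTRUE(x$trials_ok)) "ok" else "FAIL/NA", x$n_trials,
              if (x$pass) "PASS" else "fail"))
  invisible(x)
}

# ---- session files ----------------------------------------------------------
#
# Layout written/read under one directory:
#   session.json              duration + metadata
#   licks.csv                 t_detect_s, x_mm, y_mm, t_maxprot_s
#   cells/<id>.csv            t_s, kind (SS|CS)
#   cells/<id>.json           grid_row, grid_col, region_tag
#   port_trials.csv, opto_trials.csv   optional

read_numeric_col <- function(df, col, file, optional = FALSE) {
  if (!col %in% names(df)) {
    if (optional) return(NULL)
    stop("missing mandatory column '", col, "' in ", file)
  }
  suppressWarnings(as.numeric(df[[col]]))
}

check_monotonic <- function(t, file) {
  if (length(t) > 1) {
    bad <- which(diff(t) <= 0)
    if (length(bad)) {
      stop("non-monotonic time column in ", file, " at line ", bad[1] + 2,
           " (data row ", bad[1] + 1, ")")
    }
  }
  t
}

#' Write a session to a directory of plain-text event tables
#'
#' Times are written with microsecond precision and coordinates with
#' micrometre precision so that `read_session(write_session(x))` reproduces
#' all values exactly at that resolution.
#'
#' @param sess a [session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(sess, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cells"), showWarnings = FALSE)
  lk <- sess$licks
  n <- n_licks(lk)
  fmt <- function(v) ifelse(is.na(v), "NaN", sprintf("%.6f", v))
  df <- data.frame(
    t_detect_s = fmt(lk$detect_times),
    x_mm = if (is.null(lk$endpoint_x)) rep("NaN", n) else fmt(lk$endpoint_x),
    y_mm = if (is.null(lk$endpoint_y)) rep("NaN", n) else fmt(lk$endpoint_y),
    t_maxprot_s = if (is.null(lk$max_protrusion_times)) rep("NaN", n)
                  else fmt(lk$max_protrusion_times))
  utils::write.csv(df, file.path(dir, "licks.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(session_duration = lk$session_duration, metadata = sess$metadata),
    file.path(dir, "session.json"), auto_unbox = TRUE, digits = NA)
  # keep each stream strictly increasing at the 1 us file resolution
  quantise <- function(t) {
    t <- round(t, 6)
    while (length(t) > 1 && any(diff(t) <= 0)) {
      i <- which(diff(t) <= 0)
      t[i + 1] <- t[i] + 1e-6
    }
    t
  }
  for (cell in sess$cells) {
    tab <- rbind(
      data.frame(t_s = quantise(cell$ss_times),
                 kind = rep("SS", length(cell$ss_times))),
      data.frame(t_s = quantise(cell$cs_times),
                 kind = rep("CS", length(cell$cs_times))))
    tab <- tab[order(tab$t_s), , drop = FALSE]
    tab$t_s <- sprintf("%.6f", tab$t_s)
    utils::write.csv(tab, file.path(dir, "cells", paste0(cell$cell_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(grid_row = cell$grid_row, grid_col = cell$grid_col,
           region_tag = cell$region_tag),
      file.path(dir, "cells", paste0(cell$cell_id, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  for (nm in c("port_trials", "opto_trials")) {
    tb <- sess[[nm]]
    if (!is.null(tb) && nrow(tb)) {
      utils::write.csv(tb, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' Read a session from a directory of event tables
#'
#' @param dir directory written by [write_session()] (or assembled by hand
#'   with the same layout).
#' @return a [session()].
#' @export
read_session <- function(dir) {
  lick_file <- file.path(dir, "licks.csv")
  if (!file.exists(lick_file)) stop("no licks.csv in ", dir)
  df <- utils::read.csv(lick_file)
  t <- read_numeric_col(df, "t_detect_s", lick_file)
  if (anyNA(t)) stop("non-numeric t_detect_s in ", lick_file, " at line ",
                     which(is.na(t))[1] + 1)
  check_monotonic(t, lick_file)
  x <- read_numeric_col(df, "x_mm", lick_file, optional = TRUE)
  y <- read_numeric_col(df, "y_mm", lick_file, optional = TRUE)
  mp <- read_numeric_col(df, "t_maxprot_s", lick_file, optional = TRUE)
  drop_all_na <- function(v) if (is.null(v) || all(is.na(v))) NULL else v
  meta_file <- file.path(dir, "session.json")
  duration <- NULL; metadata <- list()
  if (file.exists(meta_file)) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    duration <- meta$session_duration
    metadata <- if (is.null(meta$metadata)) list() else as.list(meta$metadata)
  }
  licks <- lick_train(t, session_duration = duration,
                      endpoint_x = drop_all_na(x), endpoint_y = drop_all_na(y),
                      max_protrusion_times = drop_all_na(mp))
  cells <- list()
  cell_dir <- file.path(dir, "cells")
  if (dir.exists(cell_dir)) {
    for (f in sort(list.files(cell_dir, pattern = "\\.csv$", full.names = TRUE))) {
      id <- sub("\\.csv$", "", basename(f))
      tab <- utils::read.csv(f)
      ts <- read_numeric_col(tab, "t_s", f)
      if (!"kind" %in% names(tab)) stop("missing mandatory column 'kind' in ", f)
      # the SS and CS streams are each strictly increasing; the merged
      # column may interleave them arbitrarily closely
      check_monotonic(ts[tab$kind == "SS"], f)
      check_monotonic(ts[tab$kind == "CS"], f)
      side <- file.path(cell_dir, paste0(id, ".json"))
      gr <- NA_integer_; gc <- NA_integer_; tag <- "medial"
      if (file.exists(side)) {
        js <- jsonlite::read_json(side, simplifyVector = TRUE)
        gr <- js$grid_row %||% NA_integer_
        gc <- js$grid_col %||% NA_integer_
        tag <- js$region_tag %||% "medial"
      }
      cells[[id]] <- cell_recording(id, ts[tab$kind == "SS"],
                                    ts[tab$kind == "CS"],
                                    grid_row = gr, grid_col = gc,
                                    region_tag = tag)
    }
  }
  read_opt <- function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) utils::read.csv(f) else NULL
  }
  session(licks, cells, port_trials = read_opt("port_trials"),
          opto_trials = read_opt("opto_trials"), metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
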