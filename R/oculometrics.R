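# Moving average that tolerates NA: missing samples neither contribute to
# nor poison the window; positions that were NA stay NA.
na_moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  ok <- !is.na(x)
  num <- stats::filter(ifelse(ok, x, 0), rep(1, width), sides = 2)
  den <- stats::filter(as.numeric(ok), rep(1, width), sides = 2)
  # partial windows at the ends
  half <- (width - 1L) %/% 2L
  n <- length(x)
  for (i in c(seq_len(half), n - seq_len(half) + 1L)) {
    w <- max(1L, i - half):min(n, i + half)
    num[i] <- sum(x[w][ok[w]])
    den[i] <- sum(ok[w])
  }
  out <- as.numeric(num) / pmax(as.numeric(den), 1)
  out[!ok | as.numeric(den) == 0] <- NA_real_
  out
}

# Linear interpolation of NA runs no longer than max_gap samples; longer
# runs stay NA. Returns the filled vector and the filled-in mask.
fill_short_gaps <- function(x, max_gap) {
  n <- length(x)
  filled <- rep(FALSE, n)
  if (!anyNA(x) || all(is.na(x))) return(list(x = x, filled = filled))
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  y <- x
  for (k in which(r$values)) {
    if (r$lengths[k] > max_gap) next
    a <- starts[k] - 1L; b <- ends[k] + 1L
    if (a < 1L || b > n) next                     # gap touches a trace end
    idx <- starts[k]:ends[k]
    y[idx] <- x[a] + (x[b] - x[a]) * (idx - a) / (b - a)
    filled[idx] <- TRUE
  }
  list(x = y, filled = filled)
}

#' Clean and derive a raw eye-tracking trace
#'
#' Standard pupillometry hygiene: samples outside the physiological pupil
#' range or marked invalid are treated as missing (blinks); missing runs of
#' at most `max_gap_ms` are linearly interpolated, longer runs stay invalid;
#' the pupil signal is smoothed with a `smooth_ms` moving average; gaze
#' velocity is computed from central differences and smoothed over
#' `vel_smooth_ms`.
#'
#' @param trace data frame with `t_ms` (strictly increasing), pupil columns
#'   (`pupil_mm`, or `pupil_l_mm` / `pupil_r_mm`), optional `gaze_x_deg` /
#'   `gaze_y_deg`, optional logical `valid`.
#' @param max_gap_ms longest interpolatable missing run, ms.
#' @param pupil_range physiologically valid pupil diameters, mm.
#' @param smooth_ms pupil moving-average window, ms.
#' @param vel_smooth_ms gaze velocity smoothing window, ms.
#' @return data frame of class `clean_trace`: input columns plus `pupil_mm`
#'   (binocular mean, smoothed), per-eye smoothed columns when both eyes are
#'   present, `speed_deg_s` (when gaze present), `valid`, `interpolated`.
#' @export
preprocess_trace <- function(trace, max_gap_ms = 500, pupil_range = c(1.5, 9),
                             smooth_ms = 100, vel_smooth_ms = 20) {
  if (!nrow(trace)) stop("empty trace")
  if (is.unsorted(trace$t_ms, strictly = TRUE))
    stop("t_ms must be strictly increasing")
  dt <- stats::median(diff(trace$t_ms))
  if (nrow(trace) * dt < 1000) stop("need at least 1 s of data")
  eyes <- intersect(c("pupil_l_mm", "pupil_r_mm", "pupil_mm"), names(trace))
  if (!length(eyes)) stop("no pupil column found")
  valid <- if ("valid" %in% names(trace)) trace$valid else rep(TRUE, nrow(trace))

  max_gap <- max(1L, round(max_gap_ms / dt))
  out <- trace
  interp <- rep(FALSE, nrow(trace))
  for (e in eyes) {
    x <- trace[[e]]
    x[!valid | x < pupil_range[1] | x > pupil_range[2]] <- NA_real_
    g <- fill_short_gaps(x, max_gap)
    interp <- interp | g$filled
    out[[e]] <- na_moving_average(g$x, round(smooth_ms / dt))
  }
  for (gcol in intersect(c("gaze_x_deg", "gaze_y_deg"), names(trace))) {
    x <- trace[[gcol]]
    x[!valid] <- NA_real_
    g <- fill_short_gaps(x, max_gap)
    out[[gcol]] <- g$x
  }
  pcols <- intersect(c("pupil_l_mm", "pupil_r_mm"), names(out))
  out$pupil_mm <- if (length(pcols) == 2L)
    rowMeans(out[pcols], na.rm = TRUE) else out[[eyes[1]]]
  out$pupil_mm[is.nan(out$pupil_mm)] <- NA_real_

  if (all(c("gaze_x_deg", "gaze_y_deg") %in% names(out))) {
    n <- nrow(out)
    cd <- function(v) c(NA, (v[-(1:2)] - v[seq_len(n - 2)]) /
                          (out$t_ms[-(1:2)] - out$t_ms[seq_len(n - 2)]), NA)
    vx <- cd(out$gaze_x_deg); vy <- cd(out$gaze_y_deg)
    speed <- sqrt(vx^2 + vy^2) * 1000           # deg/s
    out$speed_deg_s <- na_moving_average(speed, max(1L, round(vel_smooth_ms / dt)))
  }
  out$valid <- !is.na(out$pupil_mm) |
    (if ("gaze_x_deg" %in% names(out)) !is.na(out$gaze_x_deg) else FALSE)
  out$interpolated <- interp
  class(out) <- c("clean_trace", "data.frame")
  out
}

#' Event-related pupil features for one stimulus block
#'
#' Baseline `B` is the mean pupil diameter over the last 3000 ms before
#' stimulus onset (the first part of the baseline phase is treated as
#' settling). Features: PDA = signed peak deflection,
#' `100 * (d_peak - B) / B` over `[onset, onset + 10000)` ms, where `d_peak`
#' is the sample deviating most from baseline in absolute value (so blunted
#' or constricting responses come out negative); CL = start of the first
#' *sustained* (`sustained_ms`) excursion of the smoothed diameter above
#' `B + 1 SD(baseline)`, censored at the window end if none; PDV = maximum
#' first derivative of the percent-change signal (%/s).
#'
#' @param clean a [preprocess_trace()] result.
#' @param block one row of a [block_schedule()] (or list with `onset_ms`).
#' @param baseline_ms baseline averaging window before onset, ms.
#' @param window_ms feature search window after onset, ms.
#' @param min_valid minimum valid fraction of the baseline window.
#' @param sustained_ms minimum time the signal must stay above the CL
#'   threshold (debounces noise crossings).
#' @return list `PDA`, `CL`, `CL_censored`, `PDV` (all `NA` when the
#'   baseline window is insufficiently valid).
#' @export
pupil_features <- function(clean, block, baseline_ms = 3000,
                           window_ms = 10000, min_valid = 0.8,
                           sustained_ms = 300) {
  onset <- block$onset_ms
  t <- clean$t_ms; p <- clean$pupil_mm
  bw <- t >= onset - baseline_ms & t < onset
  if (!any(bw) || mean(!is.na(p[bw])) < min_valid)
    return(list(PDA = NA_real_, CL = NA_real_, CL_censored = NA,
                PDV = NA_real_))
  B <- mean(p[bw], na.rm = TRUE)
  sd_b <- stats::sd(p[bw], na.rm = TRUE)
  w <- t >= onset & t < onset + window_ms
  pw <- p[w]; tw <- t[w]
  dev <- pw - B
  peak_i <- which.max(abs(dev))
  PDA <- if (length(peak_i)) 100 * dev[peak_i] / B else NA_real_
  dt <- stats::median(diff(t))
  above <- !is.na(pw) & pw > B + sd_b
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sust <- which(r$values & r$lengths * dt >= sustained_ms)
  if (length(sust)) {
    CL <- tw[starts[sust[1]]] - onset; cens <- FALSE
  } else {
    CL <- window_ms; cens <- TRUE
  }
  pct <- 100 * (pw - B) / B
  dpct <- diff(pct) / diff(tw) * 1000           # %/s
  PDV <- if (all(is.na(dpct))) NA_real_ else max(dpct, na.rm = TRUE)
  list(PDA = PDA, CL = CL, CL_censored = cens, PDV = PDV)
}

#' I-VT fixation/saccade detection
#'
#' Velocity-threshold classification: samples with gaze speed above
#' `vel_threshold` form saccades (minimum duration `min_sacc_ms`), the
#' remainder fixations (minimum `min_fix_ms`). Saccade fragments shorter than
#' the minimum are folded back into the surrounding fixation; fixations
#' shorter than their minimum are dropped. Saccade amplitude is the Euclidean
#' start-to-end displacement; peak velocity the maximum in-event speed.
#'
#' @param clean a [preprocess_trace()] result with gaze columns.
#' @param vel_threshold saccade velocity threshold, deg/s.
#' @param min_fix_ms,min_sacc_ms minimum event durations, ms.
#' @return data frame of events: `kind`, `start_ms`, `end_ms`,
#'   `duration_ms`, `amplitude_deg` (saccades), `peak_velocity` (saccades).
#' @export
detect_events <- function(clean, vel_threshold = 30, min_fix_ms = 50,
                          min_sacc_ms = 10) {
  if (!"speed_deg_s" %in% names(clean)) stop("clean trace has no gaze speed")
  ok <- !is.na(clean$speed_deg_s) & !is.na(clean$gaze_x_deg)
  if (!any(ok)) return(empty_events())
  t <- clean$t_ms; dt <- stats::median(diff(t))
  lab <- ifelse(ok & clean$speed_deg_s > vel_threshold, "saccade", "fixation")
  lab[!ok] <- NA
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  # fold too-short saccade fragments back into fixation, then re-run
  dur <- r$lengths * dt
  short_sacc <- !is.na(r$values) & r$values == "saccade" & dur < min_sacc_ms
  if (any(short_sacc)) {
    for (k in which(short_sacc)) lab[starts[k]:ends[k]] <- "fixation"
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    dur <- r$lengths * dt
  }
  keep <- !is.na(r$values) &
    ((r$values == "fixation" & dur >= min_fix_ms) |
       (r$values == "saccade" & dur >= min_sacc_ms))
  if (!any(keep)) return(empty_events())
  ev <- lapply(which(keep), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    amp <- pv <- NA_real_
    if (r$values[k] == "saccade") {
      amp <- sqrt((clean$gaze_x_deg[i1] - clean$gaze_x_deg[i0])^2 +
                    (clean$gaze_y_deg[i1] - clean$gaze_y_deg[i0])^2)
      pv <- max(clean$speed_deg_s[i0:i1], na.rm = TRUE)
    }
    data.frame(kind = r$values[k], start_ms = t[i0], end_ms = t[i1] + dt,
               duration_ms = t[i1] + dt - t[i0], amplitude_deg = amp,
               peak_velocity = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, ev)
}

empty_events <- function() {
  data.frame(kind = character(0), start_ms = numeric(0), end_ms = numeric(0),
             duration_ms = numeric(0), amplitude_deg = numeric(0),
             peak_velocity = numeric(0), stringsAsFactors = FALSE)
}

#' Gaze features for one stimulus block
#'
#' FD = mean fixation duration (ms), SV = mean saccade peak velocity
#' (deg/s), SA = mean saccade amplitude (deg) over events whose midpoint
#' falls in the stimulus window; GDE = Shannon entropy (bits) of the valid
#' gaze samples binned on an `grid_n` x `grid_n` equal-area grid over the
#' display extent.
#'
#' @param events a [detect_events()] result.
#' @param clean the [preprocess_trace()] result.
#' @param block one schedule row (`onset_ms`, `stimulus_ms`).
#' @param grid_n grid side (default 8, so GDE is bounded by 6 bits).
#' @param extent display extent `c(xmin, xmax, ymin, ymax)` in degrees.
#' @return list `FD`, `SV`, `SA`, `GDE` (all `NA` when no fixation lies in
#'   the window).
#' @export
gaze_features <- function(events, clean, block, grid_n = 8,
                          extent = c(-16, 16, -10, 10)) {
  w0 <- block$onset_ms; w1 <- block$onset_ms + block$stimulus_ms
  mid <- (events$start_ms + events$end_ms) / 2
  inw <- mid >= w0 & mid < w1
  fx <- events[inw & events$kind == "fixation", ]
  sc <- events[inw & events$kind == "saccade", ]
  if (!nrow(fx))
    return(list(FD = NA_real_, SV = NA_real_, SA = NA_real_, GDE = NA_real_))
  FD <- mean(fx$duration_ms)
  SV <- if (nrow(sc)) mean(sc$peak_velocity) else NA_real_
  SA <- if (nrow(sc)) mean(sc$amplitude_deg) else NA_real_
  sw <- clean$t_ms >= w0 & clean$t_ms < w1 &
    !is.na(clean$gaze_x_deg) & !is.na(clean$gaze_y_deg)
  GDE <- gaze_dispersion_entropy(clean$gaze_x_deg[sw], clean$gaze_y_deg[sw],
                                 grid_n, extent)
  list(FD = FD, SV = SV, SA = SA, GDE = GDE)
}

#' Gaze dispersion entropy
#'
#' Shannon entropy, in bits, of the distribution of gaze samples over an
#' equal-area spatial grid; 0 for fully concentrated gaze, `log2(grid_n^2)`
#' for a uniform spread.
#'
#' @param x,y gaze coordinates, degrees.
#' @param grid_n grid side.
#' @param extent `c(xmin, xmax, ymin, ymax)`; samples are clamped into it.
#' @return entropy in bits (`NA` when no samples).
#' @export
gaze_dispersion_entropy <- function(x, y, grid_n = 8,
                                    extent = c(-16, 16, -10, 10)) {
  if (!length(x)) return(NA_real_)
  bx <- clamp(1L + floor((x - extent[1]) / (extent[2] - extent[1]) * grid_n),
              1L, grid_n)
  by <- clamp(1L + floor((y - extent[3]) / (extent[4] - extent[3]) * grid_n),
              1L, grid_n)
  p <- table(bx + grid_n * (by - 1L)) / length(x)
  -sum(p * log2(p))
}

#' Left/right eye-movement asymmetry index
#'
#' Relative difference of the absolute pupil dilations of the two eyes:
#' `|dL - dR| / max(eps, (dL + dR) / 2)`, with `dL`, `dR` the per-eye peak
#' dilation in mm. `NA` (missing, not an error) when only one eye is
#' available.
#'
#' @param delta_l,delta_r per-eye absolute dilation, mm.
#' @param eps denominator floor, mm.
#' @return asymmetry index (unitless, non-negative) or `NA`.
#' @export
asymmetry_index <- function(delta_l, delta_r, eps = 0.05) {
  if (is.na(delta_l) || is.na(delta_r)) return(NA_real_)
  abs(delta_l - delta_r) / max(eps, (delta_l + delta_r) / 2)
}

#' Extract the full feature octet for every stimulus of a session
#'
#' Runs [pupil_features()], [detect_events()], [gaze_features()] and
#' [asymmetry_index()] per schedule block.
#'
#' @param clean a [preprocess_trace()] result.
#' @param schedule a [block_schedule()].
#' @param grid_n,extent see [gaze_features()].
#' @return data frame, one row per stimulus: `stimulus_idx`, `valence`,
#'   `PDA`, `CL`, `CL_censored`, `PDV`, `FD`, `SV`, `SA`, `GDE`, `EMA`.
#' @export
extract_features <- function(clean, schedule, grid_n = 8,
                             extent = c(-16, 16, -10, 10)) {
  has_gaze <- "speed_deg_s" %in% names(clean)
  events <- if (has_gaze) detect_events(clean) else empty_events()
  both_eyes <- all(c("pupil_l_mm", "pupil_r_mm") %in% names(clean))
  rows <- lapply(seq_len(nrow(schedule)), function(b) {
    blk <- schedule[b, ]
    pf <- pupil_features(clean, blk)
    gf <- if (has_gaze) gaze_features(events, clean, blk, grid_n, extent)
    else list(FD = NA_real_, SV = NA_real_, SA = NA_real_, GDE = NA_real_)
    ema <- NA_real_
    if (both_eyes) {
      bw <- clean$t_ms >= blk$onset_ms - 3000 & clean$t_ms < blk$onset_ms
      w <- clean$t_ms >= blk$onset_ms & clean$t_ms < blk$onset_ms + 10000
      dl <- suppressWarnings(max(clean$pupil_l_mm[w], na.rm = TRUE) -
                               mean(clean$pupil_l_mm[bw], na.rm = TRUE))
      dr <- suppressWarnings(max(clean$pupil_r_mm[w], na.rm = TRUE) -
                               mean(clean$pupil_r_mm[bw], na.rm = TRUE))
      if (is.finite(dl) && is.finite(dr)) ema <- asymmetry_index(dl, dr)
    }
    data.frame(stimulus_idx = blk$block, valence = blk$valence,
               PDA = pf$PDA, CL = pf$CL, CL_censored = pf$CL_censored,
               PDV = pf$PDV, FD = gf$FD, SV = gf$SV, SA = gf$SA,
               GDE = gf$GDE, EMA = ema, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
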