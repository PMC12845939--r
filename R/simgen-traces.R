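#' Build a block schedule
#'
#' Each stimulus block is baseline / stimulus / rest (defaults 5 s / 8 s /
#' 5 s); blocks are laid back to back. `onset_ms` is the stimulus onset (end
#' of the baseline phase).
#'
#' @param valences character vector of block valences (`"pos"`, `"neg"` or
#'   `"none"`), one per block.
#' @param baseline_ms,stimulus_ms,rest_ms phase durations in ms.
#' @return data frame of class `block_schedule` with columns `block`,
#'   `start_ms`, `onset_ms`, `baseline_ms`, `stimulus_ms`, `rest_ms`,
#'   `end_ms`, `valence`.
#' @export
block_schedule <- function(valences = c("pos", "pos", "pos", "neg", "neg", "neg"),
                           baseline_ms = 5000, stimulus_ms = 8000,
                           rest_ms = 5000) {
  if (baseline_ms <= 0 || stimulus_ms <= 0 || rest_ms <= 0)
    stop("block phase durations must be positive")
  if (!all(valences %in% c("pos", "neg", "none")))
    stop("valence must be one of 'pos', 'neg', 'none'")
  n <- length(valences)
  total <- baseline_ms + stimulus_ms + rest_ms
  start <- (seq_len(n) - 1) * total
  structure(data.frame(
    block = seq_len(n), start_ms = start, onset_ms = start + baseline_ms,
    baseline_ms = baseline_ms, stimulus_ms = stimulus_ms, rest_ms = rest_ms,
    end_ms = start + total, valence = valences, stringsAsFactors = FALSE
  ), class = c("block_schedule", "data.frame"))
}

#' Pupil event-response kernel
#'
#' Gamma-family impulse response `h(t) = (t/t_max)^n * exp(n * (1 - t/t_max))`
#' for `t >= 0` (0 otherwise): single-peaked and normalised to a unit peak at
#' exactly `t = t_max`. Defaults `n = 10.1`, `t_max = 930` ms are the standard
#' pupillometry impulse-response parameters.
#'
#' @param t_ms time since response onset, ms (vectorised).
#' @param peak_time_ms time-to-peak, ms.
#' @param shape_n dimensionless shape parameter.
#' @return kernel values in `[0, 1]`.
#' @export
pupil_kernel <- function(t_ms, peak_time_ms = 930, shape_n = 10.1) {
  if (peak_time_ms <= 0) stop("peak_time_ms must be positive")
  x <- t_ms / peak_time_ms
  out <- numeric(length(t_ms))
  pos <- t_ms > 0
  out[pos] <- x[pos]^shape_n * exp(shape_n * (1 - x[pos]))
  out
}

#' Pupil trace generator parameters
#'
#' @param baseline_diameter resting pupil diameter, mm (valid 1.5-9).
#' @param amplitude event-response amplitude, % of baseline; scalar or one
#'   value per schedule block.
#' @param latency_ms response latency after stimulus onset, ms.
#' @param peak_time_ms,shape_n kernel parameters, see [pupil_kernel()].
#' @param noise_sd additive Gaussian noise SD, mm.
#' @param blink_rate blink events per minute.
#' @param blink_duration_ms blink (missing-run) duration, ms.
#' @param sampling_rate Hz.
#' @return list of class `pupil_params`.
#' @export
pupil_params <- function(baseline_diameter = 4.0, amplitude = 15,
                         latency_ms = 400, peak_time_ms = 930, shape_n = 10.1,
                         noise_sd = 0.02, blink_rate = 6,
                         blink_duration_ms = 150, sampling_rate = 100) {
  if (baseline_diameter < 1.5 || baseline_diameter > 9)
    stop("baseline_diameter must lie in [1.5, 9] mm")
  if (peak_time_ms <= 0) stop("peak_time_ms must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(baseline_diameter = baseline_diameter, amplitude = amplitude,
                 latency_ms = latency_ms, peak_time_ms = peak_time_ms,
                 shape_n = shape_n, noise_sd = noise_sd,
                 blink_rate = blink_rate,
                 blink_duration_ms = blink_duration_ms,
                 sampling_rate = sampling_rate), class = "pupil_params")
}

#' Simulate a pupil diameter trace over a block schedule
#'
#' Diameter is `B * (1 + sum_b (A_b/100) * h(t - onset_b - latency)) + noise`
#' with the unit-peak kernel [pupil_kernel()]; blinks are inserted as missing
#' runs. Deterministic under `seed`.
#'
#' @param params a [pupil_params()]; `amplitude` may be per-block.
#' @param schedule a [block_schedule()].
#' @param seed integer seed.
#' @param both_eyes simulate left and right eye (right adds small independent
#'   noise); otherwise a single `pupil_mm` column.
#' @return data frame `t_ms`, `pupil_l_mm`, `pupil_r_mm` (or `pupil_mm`),
#'   `valid`.
#' @export
simulate_pupil_trace <- function(params, schedule, seed = 1L,
                                 both_eyes = TRUE) {
  stopifnot(inherits(params, "pupil_params"))
  dur <- max(schedule$end_ms)
  if (any(schedule$start_ms < 0)) stop("schedule outside trace duration")
  fs <- params$sampling_rate
  t_ms <- seq(0, dur - 1000 / fs, by = 1000 / fs)
  amp <- rep_len(params$amplitude, nrow(schedule))
  drive <- numeric(length(t_ms))
  for (b in seq_len(nrow(schedule))) {
    drive <- drive + (amp[b] / 100) *
      pupil_kernel(t_ms - schedule$onset_ms[b] - params$latency_ms,
                   params$peak_time_ms, params$shape_n)
  }
  with_local_seed(seed, {
    B <- params$baseline_diameter
    base <- B * (1 + drive)
    noise_l <- rnorm(length(t_ms), 0, params$noise_sd)
    pl <- base + noise_l
    pr <- if (both_eyes) base + rnorm(length(t_ms), 0, params$noise_sd) else NULL
    valid <- rep(TRUE, length(t_ms))
    n_blinks <- rpois(1, params$blink_rate * dur / 60000)
    if (n_blinks > 0) {
      onsets <- runif(n_blinks, 0, dur - params$blink_duration_ms)
      for (o in onsets) {
        idx <- t_ms >= o & t_ms < o + params$blink_duration_ms
        valid[idx] <- FALSE
        pl[idx] <- NA_real_
        if (both_eyes) pr[idx] <- NA_real_
      }
    }
    if (both_eyes)
      data.frame(t_ms = t_ms, pupil_l_mm = pl, pupil_r_mm = pr, valid = valid)
    else
      data.frame(t_ms = t_ms, pupil_mm = pl, valid = valid)
  })
}

#' Saccadic main sequence
#'
#' Saturating-exponential peak velocity
#' `v_peak(A) = vmax * (1 - exp(-A / a0))`.
#'
#' @param amplitude_deg saccade amplitude, degrees.
#' @param vmax asymptotic peak velocity, deg/s.
#' @param a0 amplitude scale constant, degrees.
#' @return peak velocity, deg/s.
#' @export
main_sequence_velocity <- function(amplitude_deg, vmax = 500, a0 = 12) {
  vmax * (1 - exp(-amplitude_deg / a0))
}

# Inverse of the main sequence: amplitude producing a given peak velocity.
main_sequence_amplitude <- function(v_peak, vmax = 500, a0 = 12) {
  v <- clamp(v_peak, 0, 0.99 * vmax)
  -a0 * log(1 - v / vmax)
}

#' Gaze trace generator parameters
#'
#' @param fixation_mean,fixation_sd fixation duration distribution, ms
#'   (`fixation_mean >= 50`).
#' @param saccade_amp_mean,saccade_amp_sd saccade amplitude distribution,
#'   degrees.
#' @param vmax,a0 main-sequence parameters, see [main_sequence_velocity()].
#' @param noise_sd fixation positional noise SD, degrees.
#' @param extent display half-extent `c(x, y)` in degrees of visual angle.
#' @param sampling_rate Hz.
#' @return list of class `gaze_params`.
#' @export
gaze_params <- function(fixation_mean = 280, fixation_sd = 60,
                        saccade_amp_mean = 8, saccade_amp_sd = 3,
                        vmax = 500, a0 = 12, noise_sd = 0.15,
                        extent = c(16, 10), sampling_rate = 100) {
  if (fixation_mean < 50) stop("fixation_mean must be at least 50 ms")
  vals <- c(fixation_mean, fixation_sd, saccade_amp_mean, saccade_amp_sd,
            vmax, a0, sampling_rate)
  if (any(vals <= 0) || noise_sd < 0) stop("gaze parameters must be positive")
  structure(list(fixation_mean = fixation_mean, fixation_sd = fixation_sd,
                 saccade_amp_mean = saccade_amp_mean,
                 saccade_amp_sd = saccade_amp_sd, vmax = vmax, a0 = a0,
                 noise_sd = noise_sd, extent = extent,
                 sampling_rate = sampling_rate), class = "gaze_params")
}

#' Simulate a gaze position trace
#'
#' Alternating fixations (Gaussian positional noise around a fixed point) and
#' saccades whose peak velocity follows the main sequence; the saccade
#' displacement profile is a raised cosine, so its peak velocity is exactly
#' `v_peak` and its duration `2 A / v_peak`. Deterministic under `seed`.
#'
#' Explicit `saccades` (data frame `onset_ms`, `amplitude_deg`,
#' `direction_rad`) override random event generation: fixations fill the gaps
#' between the listed saccades. An empty data frame yields a single fixation
#' covering the whole trace.
#'
#' @param params a [gaze_params()].
#' @param schedule a [block_schedule()] (sets trace duration).
#' @param seed integer seed.
#' @param saccades optional explicit saccade table (see Details).
#' @return data frame `t_ms`, `gaze_x_deg`, `gaze_y_deg`, `valid`.
#' @export
simulate_gaze_trace <- function(params, schedule, seed = 1L, saccades = NULL) {
  stopifnot(inherits(params, "gaze_params"))
  dur <- max(schedule$end_ms)
  fs <- params$sampling_rate
  t_ms <- seq(0, dur - 1000 / fs, by = 1000 / fs)
  ex <- params$extent
  with_local_seed(seed, {
    if (is.null(saccades)) {
      # draw events until the trace is covered
      ev <- list(); t <- 0; pos <- runif(2, -ex / 2, ex / 2); k <- 0L
      while (t < dur) {
        fdur <- max(50, rnorm(1, params$fixation_mean, params$fixation_sd))
        fdur <- min(fdur, dur - t)
        k <- k + 1L
        ev[[k]] <- list(kind = "fixation", start = t, end = t + fdur,
                        from = pos, to = pos)
        t <- t + fdur
        if (t >= dur) break
        amp <- max(0.5, rnorm(1, params$saccade_amp_mean, params$saccade_amp_sd))
        theta <- runif(1, 0, 2 * pi)
        target <- clamp(pos + amp * c(cos(theta), sin(theta)), -ex, ex)
        amp_eff <- sqrt(sum((target - pos)^2))
        if (amp_eff < 0.25) next
        vpk <- main_sequence_velocity(amp_eff, params$vmax, params$a0)
        sdur <- 2 * amp_eff / vpk * 1000
        sdur <- min(sdur, dur - t)
        k <- k + 1L
        ev[[k]] <- list(kind = "saccade", start = t, end = t + sdur,
                        from = pos, to = target)
        pos <- target
        t <- t + sdur
      }
    } else {
      ev <- list(); k <- 0L; t <- 0; pos <- c(0, 0)
      if (nrow(saccades) > 0) saccades <- saccades[order(saccades$onset_ms), ]
      for (i in seq_len(nrow(saccades))) {
        o <- saccades$onset_ms[i]
        amp <- saccades$amplitude_deg[i]
        th <- saccades$direction_rad[i]
        if (o > t) {
          k <- k + 1L
          ev[[k]] <- list(kind = "fixation", start = t, end = o,
                          from = pos, to = pos)
        }
        vpk <- main_sequence_velocity(amp, params$vmax, params$a0)
        sdur <- 2 * amp / vpk * 1000
        target <- pos + amp * c(cos(th), sin(th))
        k <- k + 1L
        ev[[k]] <- list(kind = "saccade", start = o, end = o + sdur,
                        from = pos, to = target)
        pos <- target
        t <- o + sdur
      }
      if (t < dur) {
        k <- k + 1L
        ev[[k]] <- list(kind = "fixation", start = t, end = dur,
                        from = pos, to = pos)
      }
    }

    x <- numeric(length(t_ms)); y <- numeric(length(t_ms))
    for (e in ev) {
      idx <- which(t_ms >= e$start & t_ms < e$end)
      if (!length(idx)) next
      if (e$kind == "fixation") {
        x[idx] <- e$from[1] + rnorm(length(idx), 0, params$noise_sd)
        y[idx] <- e$from[2] + rnorm(length(idx), 0, params$noise_sd)
      } else {
        # raised-cosine displacement: s(u) = u - sin(2*pi*u)/(2*pi), u in [0,1]
        u <- (t_ms[idx] - e$start) / (e$end - e$start)
        s <- u - sin(2 * pi * u) / (2 * pi)
        x[idx] <- e$from[1] + (e$to[1] - e$from[1]) * s
        y[idx] <- e$from[2] + (e$to[2] - e$from[2]) * s
      }
    }
    data.frame(t_ms = t_ms, gaze_x_deg = x, gaze_y_deg = y,
               valid = rep(TRUE, length(t_ms)))
  })
}

# Join pupil and gaze traces on the common time axis.
merge_session_trace <- function(pupil, gaze) {
  stopifnot(nrow(pupil) == nrow(gaze))
  out <- cbind(pupil[setdiff(names(pupil), "valid")],
               gaze[c("gaze_x_deg", "gaze_y_deg")],
               valid = pupil$valid & gaze$valid)
  out
}
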