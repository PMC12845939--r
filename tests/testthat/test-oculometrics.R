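test_that("preprocessing interpolates short gaps and keeps long ones invalid", {
  tr <- constant_trace()
  tr$pupil_mm[201:220] <- NA            # 200 ms gap
  cl <- preprocess_trace(tr)
  expect_false(anyNA(cl$pupil_mm))
  expect_true(all(cl$interpolated[201:220]))

  tr2 <- constant_trace()
  tr2$pupil_mm[301:380] <- NA           # 800 ms gap > 500 ms limit
  cl2 <- preprocess_trace(tr2)
  expect_true(all(is.na(cl2$pupil_mm[310:370])))

  # clean constant trace: preprocessing is the identity on the signal
  cl3 <- preprocess_trace(constant_trace())
  expect_lt(max(abs(cl3$pupil_mm - 4.0)), 1e-9)
  expect_true(all(cl3$valid))

  # out-of-range samples are treated as blinks
  tr4 <- constant_trace()
  tr4$pupil_mm[50:52] <- 12
  expect_false(anyNA(preprocess_trace(tr4)$pupil_mm))  # short, interpolated

  expect_error(preprocess_trace(constant_trace(500)), "1 s")
  expect_error(preprocess_trace(constant_trace()[0, ]), "empty")
})

test_that("pupil features recover constructed baseline-relative responses", {
  sch <- block_schedule("neg")
  blk <- sch[1, ]

  flat <- pupil_features(preprocess_trace(constant_trace()), blk)
  expect_equal(flat$PDA, 0)
  expect_equal(flat$PDV, 0)
  expect_true(flat$CL_censored)

  # fixtures at the reported group means: B = 4.00 mm
  up <- add_plateau(constant_trace(), onset_ms = blk$onset_ms + 500,
                    peak = 4.736)
  f_up <- pupil_features(preprocess_trace(up), blk)
  expect_equal(f_up$PDA, 18.4, tolerance = 1e-6)
  expect_false(f_up$CL_censored)

  down <- add_plateau(constant_trace(), onset_ms = blk$onset_ms + 500,
                      peak = 3.948)
  f_down <- pupil_features(preprocess_trace(down), blk)
  expect_equal(f_down$PDA, -1.3, tolerance = 1e-6)

  # an invalid baseline window marks features missing, without error
  holey <- constant_trace()
  bw <- holey$t_ms >= blk$onset_ms - 3000 & holey$t_ms < blk$onset_ms
  holey$pupil_mm[which(bw)[1:200]] <- NA   # 2 s of the 3 s baseline missing
  f_na <- pupil_features(preprocess_trace(holey), blk)
  expect_true(is.na(f_na$PDA))
})

test_that("simulated amplitudes round-trip through the feature extractor", {
  sch <- block_schedule("neg")
  for (a in c(-5, 0, 10, 18.4, 40)) {
    pp <- pupil_params(amplitude = a, latency_ms = 400, noise_sd = 0,
                       blink_rate = 0)
    tr <- simulate_pupil_trace(pp, sch, seed = 2)
    pf <- pupil_features(preprocess_trace(tr), sch[1, ])
    expect_lt(abs(pf$PDA - a), 0.5)
  }
})

test_that("response latency is recovered in the noise-free limit and is a
          bounded late-biased threshold crossing under noise", {
  sch <- block_schedule("neg")
  pp0 <- pupil_params(amplitude = 18.4, latency_ms = 400, noise_sd = 0,
                      blink_rate = 0)
  cl0 <- pupil_features(preprocess_trace(simulate_pupil_trace(pp0, sch, 1)),
                        sch[1, ])$CL
  expect_lt(abs(cl0 - 400), 100)

  # with measurement noise the threshold crossing trails the true onset by
  # the kernel rise time but never false-triggers early
  for (s in 1:5) {
    pp <- pupil_params(amplitude = 18.4, latency_ms = 400, noise_sd = 0.02,
                       blink_rate = 0)
    cl <- pupil_features(preprocess_trace(simulate_pupil_trace(pp, sch, s)),
                         sch[1, ])$CL
    expect_gt(cl, 400)
    expect_lt(cl, 1000)
  }
})

test_that("I-VT event detection recovers simulated saccades", {
  sch <- block_schedule("neg")
  gp <- gaze_params(noise_sd = 0)
  base <- function(g) {
    tr <- cbind(g["t_ms"], pupil_mm = 4, g[c("gaze_x_deg", "gaze_y_deg",
                                             "valid")])
    preprocess_trace(tr)
  }
  still <- base(simulate_gaze_trace(gp, sch, seed = 1, saccades =
    data.frame(onset_ms = numeric(0), amplitude_deg = numeric(0),
               direction_rad = numeric(0))))
  ev0 <- detect_events(still)
  expect_equal(sum(ev0$kind == "fixation"), 1)
  expect_equal(sum(ev0$kind == "saccade"), 0)

  one <- base(simulate_gaze_trace(gp, sch, seed = 1, saccades =
    data.frame(onset_ms = 8000, amplitude_deg = 10, direction_rad = 0)))
  ev1 <- detect_events(one)
  sc <- ev1[ev1$kind == "saccade", ]
  expect_equal(nrow(sc), 1)
  expect_lt(abs(sc$amplitude_deg - 10), 0.5)

  two <- base(simulate_gaze_trace(gp, sch, seed = 1, saccades =
    data.frame(onset_ms = c(6000, 10000), amplitude_deg = c(8, 6),
               direction_rad = c(0, pi / 2))))
  ev2 <- detect_events(two)
  expect_equal(sum(ev2$kind == "saccade"), 2)
  expect_equal(sum(ev2$kind == "fixation"), 3)

  # event-count recovery down to 2 degree amplitudes
  amps <- c(2, 3.5, 5, 8)
  many <- base(simulate_gaze_trace(gp, sch, seed = 2, saccades =
    data.frame(onset_ms = seq(4000, 13000, length.out = 4),
               amplitude_deg = amps, direction_rad = rep(c(0, pi / 2), 2))))
  expect_equal(sum(detect_events(many)$kind == "saccade"), length(amps))
})

test_that("gaze dispersion entropy follows the Shannon formula", {
  expect_equal(gaze_dispersion_entropy(rep(0, 50), rep(0, 50)), 0)

  # one sample in the middle of each of the 64 cells: uniform -> 6 bits
  gx <- rep(seq(-16, 16, length.out = 17)[-17] + 1, times = 8)
  gy <- rep(seq(-10, 10, length.out = 17)[-17] + 0.6, each = 8)
  expect_equal(gaze_dispersion_entropy(gx, gy, 8), 6.0)

  # two cells at 0.75 / 0.25
  x2 <- c(rep(-10, 75), rep(10, 25))
  e2 <- gaze_dispersion_entropy(x2, rep(0, 100), 8)
  expect_equal(e2, -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-9)
  expect_equal(round(e2, 4), 0.8113)

  # bounded by [0, 6] bits and invariant to relabelling the cells
  set.seed(4)
  x <- runif(500, -16, 16); y <- runif(500, -10, 10)
  e <- gaze_dispersion_entropy(x, y, 8)
  expect_gte(e, 0); expect_lte(e, 6)
  expect_equal(gaze_dispersion_entropy(-x, -y, 8), e, tolerance = 1e-9)
})

test_that("asymmetry index contrasts the two eyes' dilations", {
  expect_equal(asymmetry_index(0.5, 0.5), 0)
  expect_equal(asymmetry_index(0.6, 0.4), 0.4)
  expect_true(is.na(asymmetry_index(0.6, NA)))
})

test_that("baseline profiles floor the SD and demand enough sessions", {
  mk <- function(pda) data.frame(
    participant_id = "P1", session_id = paste0("S", seq_along(pda)),
    state = c("rested", "tired", "stressed")[seq_along(pda)], PDA = pda)

  same <- build_baseline(mk(c(18, 18, 18)))
  expect_equal(same$sd, max(0.05 * 18, 0.5))    # the floor, not zero

  spread <- build_baseline(mk(c(16, 18, 20)))
  expect_equal(spread$mean, 18)
  expect_equal(spread$sd, 2.0)

  expect_error(build_baseline(mk(c(16, 18))), "at least 3")
  one_state <- mk(c(16, 18, 20)); one_state$state <- "rested"
  expect_error(build_baseline(one_state), "at least 2")
})

test_that("z-scoring is baseline-relative, affine-invariant and NA-propagating", {
  prof <- structure(data.frame(participant_id = "P1", feature = "PDA",
                               mean = 18, sd = 2, n_sessions = 3,
                               states = "rested,tired"),
                    class = c("baseline_profile", "data.frame"))
  f <- data.frame(participant_id = "P1", stimulus_idx = 1:3,
                  PDA = c(18, 23, NA))
  z <- zscore_features(f, prof)
  expect_equal(z$PDA, c(0, 2.5, NA))

  # rescaling feature and profile together leaves z unchanged
  prof2 <- prof; prof2$mean <- prof$mean * 7; prof2$sd <- prof$sd * 7
  f2 <- f; f2$PDA <- f$PDA * 7
  expect_equal(zscore_features(f2, prof2)$PDA, z$PDA)

  # censored response delays propagate as missing
  profc <- prof; profc$feature <- "CL"; profc$mean <- 400; profc$sd <- 50
  fc <- data.frame(participant_id = "P1", stimulus_idx = 1:2,
                   CL = c(450, 10000), CL_censored = c(FALSE, TRUE))
  zc <- zscore_features(fc, profc)
  expect_equal(zc$CL, c(1, NA))
})

test_that("valence-specific baselines match screening stimuli on valence", {
  ref <- expand.grid(session_id = c("S1", "S2", "S3"),
                     valence = c("pos", "neg"), stringsAsFactors = FALSE)
  ref$participant_id <- "P1"
  ref$state <- rep(c("rested", "tired", "stressed"), 2)
  ref$PDA <- ifelse(ref$valence == "neg", c(17, 18, 19), c(5, 6, 7))
  prof <- build_baseline(ref)
  expect_setequal(prof$feature, c("PDA.pos", "PDA.neg"))

  scr <- data.frame(participant_id = "P1", stimulus_idx = 1:2,
                    valence = c("neg", "pos"), PDA = c(27, -2))
  z <- zscore_features(scr, prof)
  m_neg <- prof$mean[prof$feature == "PDA.neg"]
  s_neg <- prof$sd[prof$feature == "PDA.neg"]
  expect_equal(z$PDA[1], (27 - m_neg) / s_neg)
  expect_lt(z$PDA[2], 0)   # blunted positive response scores negative
})

test_that("full feature extraction covers the octet per stimulus", {
  coh <- generate_cohort(cohort_config(n_total = 2, n_depressed = 1,
                                       seed = 31), traces = TRUE)
  sid <- names(coh$traces)[4]      # a screening session
  f <- extract_features(preprocess_trace(coh$traces[[sid]]),
                        coh$schedules[[sid]])
  expect_equal(nrow(f), 6)
  expect_setequal(names(f), c("stimulus_idx", "valence", "PDA", "CL",
                              "CL_censored", "PDV", "FD", "SV", "SA", "GDE",
                              "EMA"))
  tab <- coh$features[coh$features$session_id == sid, ]
  expect_lt(max(abs(f$PDA - tab$PDA)), 2)      # extractor vs generating table
  expect_true(all(f$FD >= 50, na.rm = TRUE))
  expect_true(all(f$GDE >= 0 & f$GDE <= 6, na.rm = TRUE))
  expect_true(all(f$EMA >= 0, na.rm = TRUE))
})
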