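gt_fit <- function(im) list(pupil = list(cx = im$truth$cx, cy = im$truth$cy,
                                         r = im$truth$r_pupil),
                            limbus = list(cx = im$truth$cx, cy = im$truth$cy,
                                          r = im$truth$r_limbus))

test_that("integro-differential segmentation recovers the true circles", {
  id <- iris_identity(identity_seed = 10, intra_noise_sd = 0.02)
  for (d in c(0.10, 0.25, 0.40)) {
    im <- simulate_iris_image(id, dilation = d, seed = round(100 * d))
    fit <- locate_boundaries(im)
    expect_lt(abs(fit$pupil$cx - im$truth$cx), 1)
    expect_lt(abs(fit$pupil$cy - im$truth$cy), 1)
    expect_lt(abs(fit$pupil$r - im$truth$r_pupil), 2)
    expect_lt(abs(fit$limbus$r - im$truth$r_limbus), 2)
    # relative geometry within 3%
    expect_lt(abs(fit$pupil$r / fit$limbus$r -
                    im$truth$r_pupil / im$truth$r_limbus), 0.03)
    expect_lt(fit$pupil$r, fit$limbus$r)
  }
  expect_error(locate_boundaries(matrix(0.5, 128, 128)), "flat|contrast")
  expect_error(locate_boundaries(matrix(0.5, 32, 32)), "64x64")
})

test_that("rubber-sheet normalisation is dilation-invariant", {
  id <- iris_identity(identity_seed = 21, intra_noise_sd = 0,
                      rotation_jitter = 0)
  lo <- simulate_iris_image(id, dilation = 0.10, seed = 1)
  hi <- simulate_iris_image(id, dilation = 0.40, seed = 2)
  t_lo <- rubber_sheet(lo, locate_boundaries(lo))
  t_hi <- rubber_sheet(hi, locate_boundaries(hi))
  expect_equal(dim(t_lo), c(16L, 16L))
  expect_gt(stats::cor(as.vector(t_lo), as.vector(t_hi)), 0.9)
  expect_equal(dim(rubber_sheet(lo, gt_fit(lo), 16, 32)), c(16L, 32L))
  # sampling outside the image is an error
  bad <- gt_fit(lo); bad$limbus$r <- 80
  expect_error(rubber_sheet(lo, bad), "outside")
})

test_that("image rotation maps to a circular column shift of the texture", {
  # a 90 degree rotation about the exact image centre permutes the pixel
  # lattice, so equivariance holds to machine precision
  id <- iris_identity(identity_seed = 5, intra_noise_sd = 0)
  base <- simulate_iris_image(id, dilation = 0.2, seed = 2, rotation_deg = 0,
                              centre_jitter = 0)
  rot <- simulate_iris_image(id, dilation = 0.2, seed = 2, rotation_deg = 90,
                             centre_jitter = 0)
  tb <- rubber_sheet(base, gt_fit(base), 16, 16)
  tr <- rubber_sheet(rot, gt_fit(rot), 16, 16)
  shifted <- tr[, ((seq_len(16) - 1 + 4) %% 16) + 1]   # 4 of 16 steps = 90 deg
  mism <- min(max(abs(tb - shifted)),
              max(abs(tb - tr[, ((seq_len(16) - 1 - 4) %% 16) + 1])))
  expect_lt(mism, 1e-9)
})

test_that("phase coding produces codes of the configured length", {
  set.seed(1)
  tex16 <- matrix(rnorm(16 * 16), 16, 16)
  tex32 <- matrix(rnorm(16 * 32), 16, 32)
  c512 <- encode_iris(tex16, 512)
  c1024 <- encode_iris(tex32, 1024)
  expect_length(c512$bits, 512)
  expect_length(c1024$bits, 1024)
  expect_true(all(c512$bits %in% 0:1))
  expect_identical(encode_iris(tex16, 512)$bits, c512$bits)
  expect_equal(hamming_distance(c512, encode_iris(tex16, 512))$distance, 0)
  expect_error(encode_iris(tex16, 1024), "positions")
})

test_that("independent textures yield half-distance codes", {
  set.seed(7)
  codes <- lapply(1:60, function(i)
    encode_iris(matrix(rnorm(16 * 16), 16, 16), 512))
  pairs <- utils::combn(60, 2)
  d <- vapply(seq_len(ncol(pairs)), function(k)
    hamming_distance(codes[[pairs[1, k]]], codes[[pairs[2, k]]],
                     max_shift = 0)$distance, numeric(1))
  expect_lt(abs(mean(d) - 0.5), 0.02)
})

test_that("shift-tolerant Hamming distance matches the brute-force oracle", {
  c0 <- iris_code(rep(0L, 64), n_radial = 2, n_angular = 16)
  expect_equal(hamming_distance(c0, c0)$distance, 0)
  ones <- iris_code(rep(1L, 64), n_radial = 2, n_angular = 16)
  expect_equal(hamming_distance(c0, ones, max_shift = 0)$distance, 1)

  # 512-bit codes differing in exactly 16 bits
  set.seed(3)
  a <- sample(0:1, 512, replace = TRUE)
  b <- a; flip <- sample(512, 16); b[flip] <- 1L - b[flip]
  expect_equal(hamming_distance(iris_code(a, 16, 16), iris_code(b, 16, 16),
                                max_shift = 0)$distance, 0.03125)

  # exhaustive small-instance equivalence with an independent oracle
  set.seed(11)
  for (geom in list(c(1, 8), c(2, 8), c(1, 16), c(2, 16), c(4, 8))) {
    nr <- geom[1]; na <- geom[2]
    for (rep in 1:25) {
      x <- sample(0:1, 2 * nr * na, replace = TRUE)
      y <- sample(0:1, 2 * nr * na, replace = TRUE)
      ms <- sample(0:4, 1)
      got <- hamming_distance(iris_code(x, nr, na), iris_code(y, nr, na),
                              max_shift = ms)$distance
      expect_equal(got, oracle_hamming(x, y, na, ms))
    }
  }
  expect_error(hamming_distance(iris_code(rep(0L, 32)),
                                iris_code(rep(0L, 64))), "lengths differ")
})

test_that("distance is a symmetric [0,1] measure, improved by shift search", {
  set.seed(5)
  for (i in 1:20) {
    a <- iris_code(sample(0:1, 128, replace = TRUE), 4, 16)
    b <- iris_code(sample(0:1, 128, replace = TRUE), 4, 16)
    dab <- hamming_distance(a, b)$distance
    expect_equal(dab, hamming_distance(b, a)$distance)
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_equal(hamming_distance(a, a)$distance, 0)
  }
  # genuine rotation within the search range is fully absorbed
  tmpl <- iris_code(sample(0:1, 512, replace = TRUE), 16, 16)
  rot <- iris_code(ocugate:::shift_code_bits(tmpl$bits, 16, 3), 16, 16)
  expect_equal(hamming_distance(tmpl, rot, max_shift = 4)$distance, 0)
  expect_lte(hamming_distance(tmpl, rot, max_shift = 4)$distance,
             hamming_distance(tmpl, rot, max_shift = 0)$distance)
})

test_that("identification accepts genuine probes and rejects impostors", {
  gal <- simulate_code_gallery(n_identities = 5, n_samples = 1, seed = 2)
  enrolled <- gal$templates
  probe <- enrolled[[3]]
  res <- identify_probe(probe, enrolled)
  expect_true(res$accepted)
  expect_equal(res$distance, 0)
  expect_equal(res$best_index, 3L)

  # unknown identity: impostor distances sit near one half
  set.seed(9)
  stranger <- iris_code(sample(0:1, 512, replace = TRUE), 16, 16)
  res2 <- identify_probe(stranger, enrolled)
  expect_false(res2$accepted)
  expect_gt(res2$distance, 0.40)
  expect_lt(res2$distance, 0.55)

  # ties break to the lowest gallery index
  twin <- list(enrolled[[1]], enrolled[[1]])
  expect_equal(identify_probe(enrolled[[1]], twin)$best_index, 1L)
  expect_error(identify_probe(probe, list()), "empty")
})

test_that("genuine probes under intra-class noise are accepted reliably", {
  gal <- simulate_code_gallery(n_identities = 5, n_samples = 1, seed = 4)
  enrolled <- gal$templates
  set.seed(21)
  ok <- logical(1000)
  for (i in seq_len(1000)) {
    who <- sample(5, 1)
    b <- ocugate:::shift_code_bits(enrolled[[who]]$bits, 16, sample(-4:4, 1))
    flip <- runif(512) < 0.08
    b[flip] <- 1L - b[flip]
    r <- identify_probe(iris_code(b, 16, 16), enrolled)
    ok[i] <- r$accepted && r$best_index == who
  }
  expect_gte(mean(ok), 0.99)
})

test_that("image-level encoding separates identities", {
  ids <- lapply(1:4, function(k) iris_identity(identity_seed = 400 + k))
  enrolled <- lapply(seq_along(ids), function(k)
    iris_encode_image(simulate_iris_image(ids[[k]], 0.2, seed = k),
                      identity = k))
  probe <- iris_encode_image(simulate_iris_image(ids[[2]], 0.3, seed = 99))
  res <- identify_probe(probe, enrolled)
  expect_true(res$accepted)
  expect_equal(res$best_id, 2)
})

test_that("FAR/FRR/GAR/EER behave as proper error-rate curves", {
  ev0 <- evaluate_biometrics(c(0.1, 0.12, 0.2), c(0.4, 0.45, 0.5))
  expect_equal(ev0$eer, 0)
  x <- seq(0.1, 0.6, length.out = 50)
  ev5 <- evaluate_biometrics(x, x)
  expect_equal(ev5$eer, 0.5, tolerance = 1e-9)

  # linear-interpolation oracle on a 3-point grid
  ee <- eer_from_rates(far = c(0, 0.02, 0.10), frr = c(0.10, 0.04, 0))
  expect_equal(ee$eer, 1 / 30, tolerance = 1e-9)

  set.seed(8)
  ev <- evaluate_biometrics(rbeta(500, 2, 8), rbeta(500, 8, 2))
  expect_true(all(diff(ev$rates$FAR) >= 0))
  expect_true(all(diff(ev$rates$FRR) <= 0))
  expect_equal(ev$rates$GAR + ev$rates$FRR, rep(1, nrow(ev$rates)))
  expect_gte(ev$eer, 0); expect_lte(ev$eer, 0.5)
  expect_error(evaluate_biometrics(numeric(0), c(0.5)), "non-empty")
})

test_that("impostor scores centre on one half and drop under shift search", {
  gal <- simulate_code_gallery(n_identities = 30, n_samples = 1, seed = 6)
  codes <- gal$codes
  set.seed(13)
  pairs <- utils::combn(30, 2)[, sample(choose(30, 2), 150)]
  d0 <- vapply(seq_len(ncol(pairs)), function(k)
    hamming_distance(codes[[pairs[1, k]]], codes[[pairs[2, k]]],
                     max_shift = 0)$distance, numeric(1))
  d4 <- vapply(seq_len(ncol(pairs)), function(k)
    hamming_distance(codes[[pairs[1, k]]], codes[[pairs[2, k]]],
                     max_shift = 4)$distance, numeric(1))
  expect_lt(abs(mean(d0) - 0.5), 0.02)
  expect_lt(mean(d4), mean(d0))
  expect_true(all(d4 <= d0))
})
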