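#' Construct an iris code
#'
#' A fixed-length binary phase descriptor: 2 bits per position on an
#' `n_radial` x `n_angular` grid, so `length = 2 * n_radial * n_angular`
#' (512 or 1024 in the standard configurations). Bit order is row-major by
#' radial row, then angular position, with the (real, imaginary) phase bits
#' interleaved.
#'
#' @param bits integer/logical vector of 0/1 bits.
#' @param n_radial,n_angular code grid geometry; must satisfy
#'   `2 * n_radial * n_angular == length(bits)`.
#' @param identity optional identity label.
#' @return object of class `iris_code`.
#' @export
iris_code <- function(bits, n_radial = 1L, n_angular = length(bits) / 2L,
                      identity = NULL) {
  bits <- as.integer(bits)
  if (any(is.na(bits)) || any(bits != 0L & bits != 1L))
    stop("bits must be 0/1")
  if (2L * n_radial * n_angular != length(bits))
    stop("geometry inconsistent with code length")
  structure(list(bits = bits, n_radial = as.integer(n_radial),
                 n_angular = as.integer(n_angular), identity = identity),
            class = "iris_code")
}

#' @export
print.iris_code <- function(x, ...) {
  cat(sprintf("iris_code: %d bits (%d radial x %d angular)%s\n",
              length(x$bits), x$n_radial, x$n_angular,
              if (is.null(x$identity)) "" else paste0("  id=", x$identity)))
  invisible(x)
}

# Circularly shift a code's bit vector by `s` angular positions (2 bits per
# position), applied identically to every radial row.
shift_code_bits <- function(bits, n_angular, s) {
  m2 <- 2L * n_angular
  s <- ((s %% n_angular) + n_angular) %% n_angular
  if (s == 0L) return(bits)
  M <- matrix(bits, nrow = m2)
  idx <- ((seq_len(m2) - 1L - 2L * s) %% m2) + 1L
  as.vector(M[idx, , drop = FALSE])
}

#' Encode a normalised texture into an iris code
#'
#' Daugman-style phase coding: each radial row of the texture is band-pass
#' filtered along the (periodic) angular axis with a log-Gabor filter, and
#' each position is quantised to 2 bits by phase quadrant - the signs of the
#' real and imaginary parts of the complex response.
#'
#' @param texture a [rubber_sheet()] result (or numeric matrix,
#'   radial x angular).
#' @param n_bits code length, 512 or 1024; must equal
#'   `2 * n_radial * n_angular` of the texture grid.
#' @param f0 centre frequency of the log-Gabor filter, cycles per annulus;
#'   default scales with the angular resolution.
#' @param sigma_ratio bandwidth parameter (`sigma/f0`) of the log-Gabor.
#' @param identity optional identity label to attach.
#' @return an [iris_code()].
#' @export
encode_iris <- function(texture, n_bits = 512L, f0 = NULL, sigma_ratio = 0.5,
                        identity = NULL) {
  tx <- unclass(texture)
  if (!is.matrix(tx)) stop("texture must be a matrix")
  nr <- nrow(tx); na <- ncol(tx)
  if (2L * nr * na != n_bits)
    stop(sprintf("texture grid %dx%d holds %d positions; n_bits = %d needs %d",
                 nr, na, nr * na, n_bits, n_bits / 2L))
  if (is.null(f0)) f0 <- max(2L, round(na / 8))
  freq <- c(0, seq_len(na - 1L))
  freq <- pmin(freq, na - freq)
  H <- numeric(na)
  pos_half <- freq >= 1 & seq_len(na) <= floor(na / 2) + 1L  # analytic signal
  H[pos_half] <- exp(-(log(freq[pos_half] / f0))^2 / (2 * log(sigma_ratio)^2))
  bits <- integer(0)
  out <- matrix(0L, nrow = 2L * na, ncol = nr)
  for (r in seq_len(nr)) {
    row <- tx[r, ] - mean(tx[r, ])
    resp <- stats::fft(stats::fft(row) * H, inverse = TRUE) / na
    b <- rbind(as.integer(Re(resp) >= 0), as.integer(Im(resp) >= 0))
    out[, r] <- as.vector(b)
  }
  iris_code(as.vector(out), n_radial = nr, n_angular = na, identity = identity)
}

#' Segment, normalise and encode an eye image in one step
#'
#' @param image an `eye_image` or intensity matrix.
#' @param n_bits 512 (16 x 16 grid) or 1024 (16 x 32 grid).
#' @param identity optional identity label.
#' @inheritParams encode_iris
#' @return an [iris_code()].
#' @export
iris_encode_image <- function(image, n_bits = 512L, identity = NULL,
                              sigma_ratio = 0.5) {
  geom <- switch(as.character(n_bits),
                 "512" = c(16L, 16L), "1024" = c(16L, 32L),
                 stop("n_bits must be 512 or 1024"))
  fit <- locate_boundaries(image)
  tex <- rubber_sheet(image, fit, n_radial = geom[1], n_angular = geom[2])
  encode_iris(tex, n_bits = n_bits, sigma_ratio = sigma_ratio,
              identity = identity)
}

#' Shift-tolerant fractional Hamming distance
#'
#' The minimum, over circular angular shifts `s` in
#' `[-max_shift, +max_shift]` (one angular position = 2 bits), of the
#' fraction of differing bits. Shift tolerance absorbs in-plane rotation of
#' the eye between acquisitions.
#'
#' @param a,b [iris_code()] objects (or plain 0/1 vectors) of equal length.
#' @param max_shift maximum absolute angular shift, positions.
#' @return list with `distance` (fraction in `[0, 1]`) and `shift` (the
#'   minimising shift).
#' @export
hamming_distance <- function(a, b, max_shift = 4L) {
  if (!inherits(a, "iris_code")) a <- iris_code(a)
  if (!inherits(b, "iris_code")) b <- iris_code(b)
  if (length(a$bits) != length(b$bits)) stop("code lengths differ")
  if (a$n_angular != b$n_angular || a$n_radial != b$n_radial)
    stop("code geometries differ")
  n <- length(a$bits)
  best <- Inf; best_s <- 0L
  for (s in seq.int(-max_shift, max_shift)) {
    d <- sum(a$bits != shift_code_bits(b$bits, b$n_angular, s)) / n
    if (d < best) { best <- d; best_s <- s }
  }
  list(distance = best, shift = best_s)
}

#' Identify a probe code against a gallery
#'
#' Scores the probe against every gallery code with the shift-tolerant
#' Hamming distance; the best match is the minimum distance (ties broken by
#' lowest gallery index) and is accepted iff the distance is at or below the
#' threshold.
#'
#' @param probe an [iris_code()].
#' @param gallery non-empty list of [iris_code()]s.
#' @param threshold acceptance threshold on the normalised Hamming distance.
#' @param max_shift see [hamming_distance()].
#' @return object of class `match_result`: `best_id`, `best_index`,
#'   `distance`, `shift`, `accepted`, plus the full `distances` vector.
#' @export
identify_probe <- function(probe, gallery, threshold = 0.32, max_shift = 4L) {
  if (length(gallery) == 0L) stop("gallery is empty")
  res <- lapply(gallery, function(g) hamming_distance(probe, g, max_shift))
  d <- vapply(res, `[[`, numeric(1), "distance")
  i <- which.min(d)                      # which.min takes the first minimum
  structure(list(
    best_id = gallery[[i]]$identity %||% i,
    best_index = i, distance = d[i], shift = res[[i]]$shift,
    accepted = d[i] <= threshold, threshold = threshold, distances = d
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: best=%s  HD=%.4f (shift %d)  %s (threshold %.2f)\n",
              as.character(x$best_id), x$distance, x$shift,
              if (x$accepted) "ACCEPTED" else "REJECTED", x$threshold))
  invisible(x)
}

#' Simulate an iris-code gallery at the code level
#'
#' Generates `n_identities` random template codes and, for each, `n_samples`
#' acquisition samples derived by a random circular rotation (up to
#' `rotation_max` angular positions) plus independent bit flips with
#' probability `flip_prob` - the code-level equivalent of intra-class
#' acquisition noise.
#'
#' @param n_identities,n_samples gallery size.
#' @param n_bits code length (512 default).
#' @param n_radial radial rows of the code geometry.
#' @param flip_prob per-bit perturbation probability.
#' @param rotation_max max absolute rotation, angular positions.
#' @param seed integer seed.
#' @return list with `codes` (list of [iris_code()]s, identity-labelled) and
#'   `identity` (integer vector).
#' @export
simulate_code_gallery <- function(n_identities = 100L, n_samples = 5L,
                                  n_bits = 512L, n_radial = 16L,
                                  flip_prob = 0.08, rotation_max = 4L,
                                  seed = 1L) {
  n_angular <- as.integer(n_bits / (2L * n_radial))
  with_local_seed(substream_seed(seed, "code-gallery"), {
    codes <- vector("list", n_identities * n_samples)
    templates <- vector("list", n_identities)
    identity <- integer(length(codes))
    k <- 0L
    for (i in seq_len(n_identities)) {
      tmpl <- sample(0:1, n_bits, replace = TRUE)
      templates[[i]] <- iris_code(tmpl, n_radial, n_angular, identity = i)
      for (j in seq_len(n_samples)) {
        s <- sample(seq.int(-rotation_max, rotation_max), 1L)
        b <- shift_code_bits(tmpl, n_angular, s)
        flip <- stats::runif(n_bits) < flip_prob
        b[flip] <- 1L - b[flip]
        k <- k + 1L
        codes[[k]] <- iris_code(b, n_radial, n_angular, identity = i)
        identity[k] <- i
      }
    }
    list(codes = codes, identity = identity, templates = templates,
         rotation_max = as.integer(rotation_max))
  })
}

#' Genuine and impostor score sets for a labelled gallery
#'
#' Scores all within-identity (genuine) pairs and a random sample of
#' cross-identity (impostor) pairs with the shift-tolerant Hamming distance.
#' Because two samples of the same identity can be rotated in opposite
#' directions, pairwise matching defaults to a shift search of twice the
#' gallery's per-sample rotation jitter.
#'
#' @param gallery result of [simulate_code_gallery()] (or a list with
#'   `codes` and `identity`).
#' @param max_shift shift-search range; default `2 * rotation_max` of the
#'   gallery (falling back to 4).
#' @param n_impostor number of impostor pairs to sample.
#' @param seed seed for the impostor pair sample.
#' @return list with numeric vectors `genuine` and `impostor`.
#' @export
score_gallery <- function(gallery, max_shift = NULL, n_impostor = 10000L,
                          seed = 1L) {
  if (is.null(max_shift))
    max_shift <- if (!is.null(gallery$rotation_max))
      2L * gallery$rotation_max else 4L
  codes <- gallery$codes; id <- gallery$identity
  n <- length(codes)
  pair_dist <- function(i, j)
    hamming_distance(codes[[i]], codes[[j]], max_shift)$distance
  gen <- numeric(0)
  for (g in unique(id)) {
    ix <- which(id == g)
    if (length(ix) < 2) next
    pr <- utils::combn(ix, 2)
    gen <- c(gen, vapply(seq_len(ncol(pr)),
                         function(k) pair_dist(pr[1, k], pr[2, k]), numeric(1)))
  }
  imp <- with_local_seed(substream_seed(seed, "impostor-pairs"), {
    out <- numeric(n_impostor)
    for (k in seq_len(n_impostor)) {
      repeat {
        ij <- sample.int(n, 2L)
        if (id[ij[1]] != id[ij[2]]) break
      }
      out[k] <- pair_dist(ij[1], ij[2])
    }
    out
  })
  list(genuine = gen, impostor = imp)
}
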