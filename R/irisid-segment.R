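# Bilinear interpolation of an image (matrix, row = y, col = x) at
# continuous coordinates. Returns NA outside the grid.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  wx <- x - x0; wy <- y - y0
  v <- (1 - wy) * ((1 - wx) * img[cbind(y0, x0)] + wx * img[cbind(y0, x0 + 1)]) +
    wy * ((1 - wx) * img[cbind(y0 + 1, x0)] + wx * img[cbind(y0 + 1, x0 + 1)])
  out[ok] <- v
  out
}

# Mean intensity on circles (cx, cy, r) for a vector of radii.
circular_means <- function(img, cx, cy, radii, n_angles = 64L) {
  th <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  xs <- outer(radii, cos(th)) + cx
  ys <- outer(radii, sin(th)) + cy
  v <- bilinear_sample(img, as.vector(xs), as.vector(ys))
  rowMeans(matrix(v, nrow = length(radii)), na.rm = TRUE)
}

# Gaussian blur of a 1-d signal (reflective ends).
blur1d <- function(x, sigma = 1) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2)); k <- k / sum(k)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1L]))
  as.numeric(stats::filter(xp, k, sides = 2))[half + seq_along(x)]
}

# One pass of the integro-differential operator: over a grid of candidate
# centres and radii, maximise the blurred radial derivative of the circular
# mean intensity. Returns the best (cx, cy, r) and its edge score.
id_operator <- function(img, cxs, cys, radii, n_angles = 64L, sigma = 1) {
  best <- list(score = -Inf)
  for (cx in cxs) for (cy in cys) {
    m <- circular_means(img, cx, cy, radii, n_angles)
    if (all(is.na(m))) next
    d <- blur1d(c(NA, diff(m)) / c(NA, diff(radii)), sigma)
    i <- which.max(abs(d))
    if (length(i) && !is.na(d[i]) && abs(d[i]) > best$score) {
      r <- radii[i]
      # sub-pixel refinement: parabola through the edge response at i-1, i, i+1
      if (i > 1L && i < length(d) && !is.na(d[i - 1]) && !is.na(d[i + 1])) {
        y0 <- abs(d[i - 1]); y1 <- abs(d[i]); y2 <- abs(d[i + 1])
        den <- y0 - 2 * y1 + y2
        if (den < 0) r <- r + 0.5 * (y0 - y2) / den * (radii[2] - radii[1])
      }
      best <- list(cx = cx, cy = cy, r = r, score = abs(d[i]))
    }
  }
  best
}

#' Locate pupil and limbus boundaries
#'
#' Deterministic Daugman-style integro-differential boundary fit: the pupil
#' circle maximises the blurred radial derivative of the normalised circular
#' line integral of image intensity; the limbus is fit second, constrained to
#' a larger radius around the pupil centre. Intended for images with clean
#' circular geometry (the synthetic renderer); the segmentation interface is
#' pluggable, so a learned segmenter can stand in for real imagery.
#'
#' @param image an `eye_image` or plain intensity matrix with values in
#'   `[0, 1]`.
#' @param n_angles angular samples of the line integral.
#' @return object of class `boundary_fit`: list with `pupil` and `limbus`
#'   (each `cx`, `cy`, `r`), and `score`.
#' @export
locate_boundaries <- function(image, n_angles = 64L) {
  img <- if (inherits(image, "eye_image")) image$pixels else image
  if (!is.matrix(img) || any(!is.finite(img)))
    stop("image must be a finite intensity matrix")
  if (nrow(img) < 64 || ncol(img) < 64) stop("image must be at least 64x64")
  s <- min(dim(img))
  dark <- which(img < 0.25, arr.ind = TRUE)
  if (nrow(dark) < 10 || stats::sd(img) < 0.02)
    stop("no circular contrast edge found (flat or featureless image)")
  cy0 <- mean(dark[, 1]); cx0 <- mean(dark[, 2])

  refine <- function(fit, span = 2) {
    id_operator(img, seq(fit$cx - 1, fit$cx + 1, by = 0.5),
                seq(fit$cy - 1, fit$cy + 1, by = 0.5),
                seq(max(3, fit$r - span), fit$r + span, by = 0.25), n_angles)
  }
  cxs <- round(cx0) + (-3:3); cys <- round(cy0) + (-3:3)
  rad_p <- seq(5, floor(0.45 * s / 2) * 2, by = 1)
  pup <- id_operator(img, cxs, cys, rad_p, n_angles)
  if (!is.finite(pup$score) || pup$score < 0.02)
    stop("no circular contrast edge found for the pupil")
  pup <- refine(pup)

  cxs2 <- pup$cx + (-1:1); cys2 <- pup$cy + (-1:1)
  rad_l <- seq(ceiling(pup$r * 1.15), floor(s / 2) - 2, by = 1)
  if (length(rad_l) < 3) stop("no admissible limbus radius range")
  lim <- id_operator(img, cxs2, cys2, rad_l, n_angles)
  if (!is.finite(lim$score) || lim$score < 0.02)
    stop("no circular contrast edge found for the limbus")
  lim <- refine(lim)

  structure(list(pupil = list(cx = pup$cx, cy = pup$cy, r = pup$r),
                 limbus = list(cx = lim$cx, cy = lim$cy, r = lim$r),
                 score = c(pupil = pup$score, limbus = lim$score)),
            class = "boundary_fit")
}

#' @export
print.boundary_fit <- function(x, ...) {
  cat(sprintf("boundary_fit: pupil (%.1f, %.1f, r=%.1f); limbus (%.1f, %.1f, r=%.1f)\n",
              x$pupil$cx, x$pupil$cy, x$pupil$r,
              x$limbus$cx, x$limbus$cy, x$limbus$r))
  invisible(x)
}

#' Rubber-sheet normalisation of the iris annulus
#'
#' Daugman's homogeneous rubber-sheet model: the annulus between the pupil
#' and limbus circles is resampled onto a fixed pseudo-polar grid,
#' `r(theta, rho) = (1 - rho) * R_pupil + rho * R_limbus`, with `rho` at
#' `n_radial` mid-point offsets in (0, 1) and `theta` at `n_angular` uniform
#' angles in `[0, 2*pi)`. The result is dilation-invariant: the same iris at
#' different pupil sizes maps to (nearly) the same texture.
#'
#' @param image an `eye_image` or intensity matrix.
#' @param fit a [locate_boundaries()] result (or compatible list).
#' @param n_radial,n_angular output grid size.
#' @return `n_radial` x `n_angular` matrix of class `normalized_texture`.
#' @export
rubber_sheet <- function(image, fit, n_radial = 16L, n_angular = 16L) {
  img <- if (inherits(image, "eye_image")) image$pixels else image
  if (fit$pupil$r >= fit$limbus$r) stop("pupil radius must be below limbus radius")
  rho <- (seq_len(n_radial) - 0.5) / n_radial
  th <- 2 * pi * (seq_len(n_angular) - 1L) / n_angular
  # interpolate centre and radius between the two (possibly offset) circles
  cx <- (1 - rho) * fit$pupil$cx + rho * fit$limbus$cx
  cy <- (1 - rho) * fit$pupil$cy + rho * fit$limbus$cy
  r <- (1 - rho) * fit$pupil$r + rho * fit$limbus$r
  xs <- outer(r, cos(th)) + cx
  ys <- outer(r, sin(th)) + cy
  v <- bilinear_sample(img, as.vector(xs), as.vector(ys))
  if (any(is.na(v))) stop("rubber-sheet sampling fell outside the image")
  structure(matrix(v, n_radial, n_angular), class = "normalized_texture")
}
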