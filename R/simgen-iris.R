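#' Iris identity parameters
#'
#' An identity is a seeded band-limited texture field on the normalised
#' (angle x radius) annulus; renders of the same identity differ only by
#' pupil dilation, in-plane rotation jitter and acquisition noise.
#'
#' @param identity_seed integer; fixes the identity texture.
#' @param n_radial,n_angular resolution of the latent texture grid.
#' @param band_low,band_high angular spatial-frequency band (cycles per
#'   annulus) carrying the texture energy.
#' @param pupil_radius_base undilated pupil radius, px; the rendered pupil
#'   radius is `pupil_radius_base * (1 + dilation)`.
#' @param limbus_radius iris outer (limbus) radius, px.
#' @param dilation_range admissible dilation fractions (default 0.10-0.40).
#' @param intra_noise_sd per-pixel acquisition noise SD (intensity units).
#' @param rotation_jitter max absolute in-plane rotation, degrees.
#' @param image_size rendered image side, px.
#' @return list of class `iris_identity`.
#' @export
iris_identity <- function(identity_seed = 1L, n_radial = 8L, n_angular = 256L,
                          band_low = 2L, band_high = 32L,
                          pupil_radius_base = 18, limbus_radius = 52,
                          dilation_range = c(0.10, 0.40),
                          intra_noise_sd = 0.02, rotation_jitter = 3,
                          image_size = 128L) {
  if (dilation_range[1] < 0 || dilation_range[2] >= 1 ||
      dilation_range[1] > dilation_range[2])
    stop("dilation_range must lie within [0, 1)")
  if (pupil_radius_base * (1 + dilation_range[2]) >= limbus_radius)
    stop("pupil radius must stay below the limbus radius at maximal dilation")
  if (limbus_radius >= image_size / 2)
    stop("limbus radius must fit inside the image")
  structure(list(identity_seed = as.integer(identity_seed),
                 n_radial = as.integer(n_radial),
                 n_angular = as.integer(n_angular),
                 band_low = as.integer(band_low),
                 band_high = as.integer(band_high),
                 pupil_radius_base = pupil_radius_base,
                 limbus_radius = limbus_radius,
                 dilation_range = dilation_range,
                 intra_noise_sd = intra_noise_sd,
                 rotation_jitter = rotation_jitter,
                 image_size = as.integer(image_size)),
            class = "iris_identity")
}

# Latent texture field of an identity: unit-variance noise band-passed along
# the angular axis (periodic), indexed by (radial row, angular column).
identity_texture_field <- function(id) {
  with_local_seed(substream_seed(id$identity_seed, "iris-texture"), {
    raw <- matrix(rnorm(id$n_radial * id$n_angular), id$n_radial, id$n_angular)
    na <- id$n_angular
    keep <- rep(0, na)
    freqs <- c(0, seq_len(na - 1))
    freqs <- pmin(freqs, na - freqs)          # symmetric frequency index
    keep[freqs >= id$band_low & freqs <= id$band_high] <- 1
    out <- t(apply(raw, 1, function(row) Re(stats::fft(stats::fft(row) * keep,
                                                       inverse = TRUE) / na)))
    out / stats::sd(out)                       # unit scale
  })
}

#' Render a synthetic eye image
#'
#' Renders concentric pupil (dark disc) and limbus circles at known
#' ground-truth geometry, with the identity's band-limited texture painted on
#' the annulus as a function of angle and *normalised* radius - so the
#' texture is dilation-invariant by construction, as a rubber-sheet model
#' assumes. Acquisition effects: in-plane rotation jitter, small centre
#' jitter, per-pixel Gaussian noise.
#'
#' @param id an [iris_identity()].
#' @param dilation pupil dilation fraction; must lie in `id$dilation_range`.
#' @param seed acquisition seed (noise, jitter); the identity texture depends
#'   only on `id$identity_seed`.
#' @param rotation_deg override the random rotation jitter with a fixed
#'   rotation (degrees), e.g. for rotation-equivariance checks.
#' @param centre_jitter max absolute random offset of the eye centre, px
#'   (0 pins the centre to the image midpoint).
#' @return object of class `eye_image`: list with `pixels` (matrix in
#'   `[0, 1]`) and `truth` (list `cx`, `cy`, `r_pupil`, `r_limbus`,
#'   `rotation_deg`, `dilation`).
#' @export
simulate_iris_image <- function(id, dilation = 0.2, seed = 1L,
                                rotation_deg = NULL, centre_jitter = 2) {
  stopifnot(inherits(id, "iris_identity"))
  if (dilation < id$dilation_range[1] || dilation > id$dilation_range[2])
    stop("dilation outside the configured dilation_range")
  tex <- identity_texture_field(id)
  s <- id$image_size
  with_local_seed(seed, {
    rot <- if (is.null(rotation_deg))
      stats::runif(1, -id$rotation_jitter, id$rotation_jitter) else rotation_deg
    cx <- s / 2 + stats::runif(1, -centre_jitter, centre_jitter)
    cy <- s / 2 + stats::runif(1, -centre_jitter, centre_jitter)
    r_p <- id$pupil_radius_base * (1 + dilation)
    r_l <- id$limbus_radius
    if (r_p >= r_l) stop("pupil radius must stay below the limbus radius")

    xs <- matrix(rep(seq_len(s), each = s), s, s)   # column index
    ys <- matrix(rep(seq_len(s), times = s), s, s)  # row index
    dx <- xs - cx; dy <- ys - cy
    r <- sqrt(dx^2 + dy^2)
    theta <- (atan2(dy, dx) - rot * pi / 180) %% (2 * pi)

    img <- matrix(0.85, s, s)                       # sclera
    in_pupil <- r <= r_p
    in_iris <- r > r_p & r <= r_l
    img[in_pupil] <- 0.05
    # normalised radial coordinate on the annulus
    rho <- (r[in_iris] - r_p) / (r_l - r_p)
    ti <- clamp(rho * (id$n_radial - 1) + 1, 1, id$n_radial)
    tj <- theta[in_iris] / (2 * pi) * id$n_angular + 1
    i0 <- floor(ti); i1 <- pmin(i0 + 1, id$n_radial); wi <- ti - i0
    j0 <- floor(tj); wj <- tj - j0
    j0 <- (j0 - 1) %% id$n_angular + 1
    j1 <- j0 %% id$n_angular + 1
    val <- (1 - wi) * ((1 - wj) * tex[cbind(i0, j0)] + wj * tex[cbind(i0, j1)]) +
      wi * ((1 - wj) * tex[cbind(i1, j0)] + wj * tex[cbind(i1, j1)])
    img[in_iris] <- clamp(0.5 + 0.16 * val, 0, 1)
    if (id$intra_noise_sd > 0)
      img <- clamp(img + matrix(stats::rnorm(s * s, 0, id$intra_noise_sd), s, s),
                   0, 1)
    structure(list(pixels = img,
                   truth = list(cx = cx, cy = cy, r_pupil = r_p,
                                r_limbus = r_l, rotation_deg = rot,
                                dilation = dilation)),
              class = "eye_image")
  })
}

#' @export
print.eye_image <- function(x, ...) {
  cat(sprintf("eye_image %dx%d  pupil r=%.1f  limbus r=%.1f  rotation %.2f deg\n",
              nrow(x$pixels), ncol(x$pixels), x$truth$r_pupil,
              x$truth$r_limbus, x$truth$rotation_deg))
  invisible(x)
}
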