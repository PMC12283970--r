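## Fluorescence-video rendering (video track).
##
## Particles are rendered as diffraction-limited spots with an Airy-disk
## PSF (FWHM 2.1 px), on a constant background of 100 counts, corrupted
## with Poisson shot noise and stored as 8-bit frames. The PSF is truncated
## at its third dark ring and renormalized by the encircled energy inside
## the truncation radius, so an isolated spot integrates to the particle's
## per-frame intensity.

## Airy pattern I(v) = (2 J1(v)/v)^2: half max at v = 1.6163396,
## dark rings at the zeros of J1 (3.8317, 7.0156, 10.1735, ...)
AIRY_V_HALF <- 1.6163396
AIRY_V_RING3 <- 10.173468

#' Imaging configuration for video rendering
#'
#' @param I_bg constant background, counts/pixel.
#' @param FWHM_PSF full width at half maximum of the Airy PSF, pixels.
#' @param I_min,I_max bounds of the per-particle total-intensity uniform
#'   draw, counts.
#' @param sigma_I per-frame intensity fluctuation SD, counts.
#' @param frame_size frame side, pixels.
#' @param n_frames frames per video.
#' @param vip_radius radius of the VIP label disks, pixels (default one
#'   FWHM).
#' @return list of class `"imaging_config"`.
#' @export
imaging_config <- function(I_bg = 100, FWHM_PSF = 2.1,
                           I_min = 400, I_max = 600, sigma_I = 20,
                           frame_size = 128, n_frames = 200,
                           vip_radius = FWHM_PSF) {
  if (I_min > I_max) stop("I_min must not exceed I_max", call. = FALSE)
  if (min(I_bg, I_min, I_max, sigma_I) < 0) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(
      I_bg = I_bg, FWHM_PSF = FWHM_PSF, I_min = I_min, I_max = I_max,
      sigma_I = sigma_I, frame_size = as.integer(frame_size),
      n_frames = as.integer(n_frames), vip_radius = vip_radius
    ),
    class = "imaging_config"
  )
}

## normalized, truncated Airy PSF evaluated at radial distance r (pixels);
## integrates to ~1 over the plane
airy_psf <- function(r, fwhm) {
  k <- 2 * AIRY_V_HALF / fwhm
  v <- k * r
  val <- ifelse(v < 1e-8, 1, (2 * besselJ(pmax(v, 1e-8), 1) / pmax(v, 1e-8))^2)
  val[v > AIRY_V_RING3] <- 0
  ee <- 1 - besselJ(AIRY_V_RING3, 0)^2 - besselJ(AIRY_V_RING3, 1)^2
  val * k^2 / (4 * pi) / ee
}

#' Draw per-particle, per-frame emission intensities
#'
#' Each particle's base intensity is uniform on `[I_min, I_max]`; the
#' per-frame value fluctuates as `Normal(I_i, sigma_I)`, clipped at 0.
#'
#' @param n_particles number of particles.
#' @param config an [imaging_config()].
#' @param seed optional integer seed.
#' @return tibble with columns `particle`, `frame` (0-based), `intensity`.
#' @export
sample_intensities <- function(n_particles, config = imaging_config(),
                               seed = NULL) {
  with_seed(seed, {
    base <- stats::runif(n_particles, config$I_min, config$I_max)
    nf <- config$n_frames
    tibble::tibble(
      particle = rep(seq_len(n_particles), each = nf),
      frame = rep(0:(nf - 1L), times = n_particles),
      intensity = pmax(
        0,
        stats::rnorm(n_particles * nf, rep(base, each = nf), config$sigma_I)
      )
    )
  })
}

#' Render one noiseless expected-count frame
#'
#' `image = I_bg + sum_i intensity_i * AiryPSF(position_i)`, with pixel
#' centers at integer coordinates `0..frame_size-1`.
#'
#' @param positions matrix or data frame with columns `x`, `y` (sub-pixel,
#'   FOV coordinates); may have zero rows.
#' @param intensities per-particle total intensities, counts.
#' @param config an [imaging_config()].
#' @return `frame_size x frame_size` numeric matrix of expected counts.
#' @export
render_frame <- function(positions, intensities, config = imaging_config()) {
  S <- config$frame_size
  img <- matrix(config$I_bg, S, S)
  if (is.null(positions) || NROW(positions) == 0) {
    return(img)
  }
  pos <- as.data.frame(positions)
  rmax <- AIRY_V_RING3 * config$FWHM_PSF / (2 * AIRY_V_HALF)
  w <- ceiling(rmax)
  for (i in seq_len(nrow(pos))) {
    px <- pos$x[i]
    py <- pos$y[i]
    # matrix row = y pixel + 1, column = x pixel + 1
    xs <- max(0, floor(px - w)):min(S - 1, ceiling(px + w))
    ys <- max(0, floor(py - w)):min(S - 1, ceiling(py + w))
    if (length(xs) == 0 || length(ys) == 0) next
    r <- sqrt(outer((ys - py)^2, (xs - px)^2, `+`))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] +
      intensities[i] * airy_psf(r, config$FWHM_PSF)
  }
  img
}

#' Corrupt an expected-count image with Poisson shot noise
#'
#' @param expected non-negative numeric matrix of expected counts.
#' @param seed optional integer seed.
#' @return integer-valued matrix, each pixel `~ Poisson(expected)`.
#' @export
corrupt_with_noise <- function(expected, seed = NULL) {
  if (any(expected < 0)) {
    stop("expected counts must be non-negative", call. = FALSE)
  }
  with_seed(seed, {
    matrix(
      stats::rpois(length(expected), as.vector(expected)),
      nrow(expected), ncol(expected)
    )
  })
}

#' Quantize a count image to 8 bits
#'
#' Values are clipped to `[0, 255]` and rounded to integers (no rescaling:
#' counts are already in detector units). The fraction of clipped pixels is
#' attached as attribute `"clip_frac"` so saturation can be monitored.
#'
#' @param img non-negative numeric matrix.
#' @return integer matrix in `[0, 255]` with attribute `clip_frac`.
#' @export
quantize_to_8bit <- function(img) {
  if (any(img < 0)) stop("counts must be non-negative", call. = FALSE)
  out <- round(img)
  clip <- mean(out > 255)
  out[out > 255] <- 255L
  storage.mode(out) <- "integer"
  attr(out, "clip_frac") <- clip
  out
}

#' Peak intensity of a spot from its total intensity
#'
#' `I_peak = I_tot * 4 ln 2 / (pi * FWHM^2)` (the peak of a Gaussian-
#' equivalent spot carrying `I_tot` photons).
#'
#' @param I_tot total collected intensity, counts.
#' @param FWHM PSF full width at half maximum, pixels.
#' @return peak counts.
#' @export
peak_from_total <- function(I_tot, FWHM) {
  I_tot * 4 * log(2) / (pi * FWHM^2)
}

#' Signal-to-noise ratio of a rendered spot
#'
#' Average peak intensity over the shot-noise SD at the peak:
#' `SNR = I_peak / sqrt(I_peak + I_bg)`.
#'
#' @param I_peak peak intensity, counts.
#' @param I_bg background, counts.
#' @return SNR (0 when `I_peak = 0`).
#' @export
snr <- function(I_peak, I_bg) {
  if (any(I_peak < 0) || any(I_bg < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  ifelse(I_peak == 0, 0, I_peak / sqrt(I_peak + I_bg))
}

#' Build the VIP label map for the first frame
#'
#' A disk of radius `config$vip_radius` around each VIP particle's
#' first-frame position is filled with the particle index; where disks
#' overlap, each pixel takes the nearest center's label.
#'
#' @param positions data frame with columns `particle`, `x`, `y`
#'   (first-frame positions, FOV coordinates).
#' @param vip_ids particle indices to label (subset of
#'   `positions$particle`).
#' @param config an [imaging_config()].
#' @return integer `frame_size x frame_size` matrix; background 0.
#' @export
make_vip_map <- function(positions, vip_ids, config = imaging_config()) {
  S <- config$frame_size
  lab <- matrix(0L, S, S)
  if (length(vip_ids) == 0) {
    return(lab)
  }
  if (!all(vip_ids %in% positions$particle)) {
    stop("vip_ids must be present in positions", call. = FALSE)
  }
  dmin <- matrix(Inf, S, S)
  R <- config$vip_radius
  for (id in vip_ids) {
    row <- positions[positions$particle == id, , drop = FALSE][1, ]
    xs <- max(0, floor(row$x - R)):min(S - 1, ceiling(row$x + R))
    ys <- max(0, floor(row$y - R)):min(S - 1, ceiling(row$y + R))
    if (length(xs) == 0 || length(ys) == 0) next
    d <- sqrt(outer((ys - row$y)^2, (xs - row$x)^2, `+`))
    sel <- d <= R & d < dmin[ys + 1, xs + 1]
    sub <- lab[ys + 1, xs + 1]
    sub[sel] <- as.integer(id)
    lab[ys + 1, xs + 1] <- sub
    dsub <- dmin[ys + 1, xs + 1]
    dsub[sel] <- d[sel]
    dmin[ys + 1, xs + 1] <- dsub
  }
  lab
}

#' Render a cropped trajectory set as a noisy 8-bit video
#'
#' Full video pipeline: per-particle intensities, Airy-disk rendering of
#' every in-FOV particle per frame, Poisson corruption, 8-bit quantization,
#' plus the VIP label map of the first frame.
#'
#' @param fov_traj tibble from [crop_to_fov()] (columns `traj`, `frame`,
#'   `x`, `y`).
#' @param config an [imaging_config()].
#' @param vip_ids trajectory ids to mark as VIPs; default all trajectories
#'   present at the first frame.
#' @param seed optional integer seed.
#' @return list with `frames` (list of `n_frames` integer matrices),
#'   `vip_map` (integer matrix), `clip_frac` (mean fraction of saturated
#'   pixels).
#' @export
render_video <- function(fov_traj, config = imaging_config(),
                         vip_ids = NULL, seed = NULL) {
  with_seed(seed, {
    ids <- sort(unique(fov_traj$traj))
    inten <- sample_intensities(length(ids), config)
    inten$particle <- ids[inten$particle]
    frames <- vector("list", config$n_frames)
    clip <- numeric(config$n_frames)
    for (f in seq_len(config$n_frames) - 1L) {
      here <- fov_traj[fov_traj$frame == f, , drop = FALSE]
      ints <- inten$intensity[match(
        paste(here$traj, f),
        paste(inten$particle, inten$frame)
      )]
      expected <- render_frame(here[, c("x", "y")], ints, config)
      q <- quantize_to_8bit(corrupt_with_noise(expected))
      clip[f + 1] <- attr(q, "clip_frac")
      frames[[f + 1]] <- q
    }
    first <- fov_traj[fov_traj$frame == min(fov_traj$frame), , drop = FALSE]
    vip_ids <- vip_ids %||% first$traj
    vip_ids <- intersect(vip_ids, first$traj)
    vip <- make_vip_map(
      tibble::tibble(particle = first$traj, x = first$x, y = first$y),
      vip_ids, config
    )
    list(frames = frames, vip_map = vip, clip_frac = mean(clip))
  })
}
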