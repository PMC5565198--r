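## -------------------------------------------------------------------------
## Orientation-noise probe synthesis, grafting, and global scene
## manipulations (filtering, warping, cut-out/lines, scrambling, gaps).
## -------------------------------------------------------------------------

## run expr with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Probe specification
#'
#' Parameters of the 16-channel orientation probe: the signal class q
#' (1 congruent, 0 incongruent), target intensity rho, and the orientation-
#' noise distribution (contrast fractions of the background luminance).
#' Channel k (1-based) sits at orientation \code{congruent_theta +
#' (k - 5) * pi/16} mod pi, so channel 5 is the congruent channel and
#' channel 13 the incongruent one (pi/2 away).
#'
#' @param q signal class, 0 or 1.
#' @param rho target intensity (contrast fraction), >= 0.
#' @param noise_mean,noise_sd Gaussian orientation-noise mean and SD in
#'   contrast units (defaults 0.03 and 0.007).
#' @param clip_sd noise clipped to mean +/- clip_sd * SD (default 4).
#' @param carrier_freq carrier spatial frequency, cycles/degree (default 1).
#' @param flat_diam diameter of the flat envelope region, degrees (1.6).
#' @param skirt_sd SD of the Gaussian envelope skirt, degrees (0.1).
#' @param phase_seed integer seed for the 16 random carrier phases.
#' @return object of class \code{probe_spec}.
#' @export
probe_spec <- function(q = 1, rho = 0.12, noise_mean = 0.03,
                       noise_sd = 0.007, clip_sd = 4, carrier_freq = 1,
                       flat_diam = 1.6, skirt_sd = 0.1, phase_seed = 1L) {
  if (!q %in% c(0, 1)) sp_input_error("q must be 0 or 1")
  if (rho < 0) sp_input_error("rho must be >= 0")
  if (noise_mean < 0 || noise_sd < 0) sp_input_error("noise parameters must be >= 0")
  structure(list(q = q, rho = rho, noise_mean = noise_mean,
                 noise_sd = noise_sd, clip_sd = clip_sd,
                 carrier_freq = carrier_freq, flat_diam = flat_diam,
                 skirt_sd = skirt_sd, phase_seed = as.integer(phase_seed)),
            class = "probe_spec")
}

#' Target signal vector
#'
#' All-zero 16-vector except the congruent channel (entry 5) for q = 1 or
#' the incongruent channel (entry 13) for q = 0, which carries rho.
#'
#' @param q signal class, 0 or 1.
#' @param rho target intensity.
#' @return numeric vector, length 16.
#' @export
make_target <- function(q, rho) {
  if (!isTRUE(q %in% c(0, 1))) sp_input_error("q must be 0 or 1")
  if (rho < 0) sp_input_error("rho must be >= 0")
  t <- numeric(16)
  t[if (q == 1) 5L else 13L] <- rho
  t
}

#' Sample an orientation-noise vector
#'
#' 16 i.i.d. Gaussian draws (mean \code{noise_mean}, SD \code{noise_sd}),
#' clipped to mean +/- \code{clip_sd} * SD.
#'
#' @param spec a [probe_spec].
#' @return numeric vector, length 16.
#' @export
sample_noise <- function(spec) {
  n <- stats::rnorm(16, spec$noise_mean, spec$noise_sd)
  lo <- spec$noise_mean - spec$clip_sd * spec$noise_sd
  hi <- spec$noise_mean + spec$clip_sd * spec$noise_sd
  pmin(pmax(n, lo), hi)
}

## 16 channel orientations for a given congruent orientation
channel_orientations <- function(congruent_theta) {
  (congruent_theta + (1:16 - 5) * pi / 16) %% pi
}

## compound envelope: flat disc + Gaussian skirt; r in degrees
probe_envelope_r <- function(r, flat_diam, skirt_sd) {
  R <- flat_diam / 2
  ifelse(r <= R, 1, exp(-(r - R)^2 / (2 * skirt_sd^2)))
}

## patch side (odd, px) covering flat region + 4 SD of skirt
probe_patch_side <- function(spec, geometry) {
  odd_px(spec$flat_diam + 8 * spec$skirt_sd, geometry)
}

## cosine/sine carrier basis for the 16 channels over the patch grid, each
## already multiplied by the envelope. Returns npix x 32 matrix [C | S]:
## patch = C %*% (s * cos(phi)) - S %*% (s * sin(phi)).
probe_carrier_basis <- function(spec, congruent_theta, geometry,
                                side = probe_patch_side(spec, geometry)) {
  h <- (side - 1) / 2
  dpp <- geometry$deg_per_px
  g <- coord_grids(side, side, center = c(h, h))
  x <- g$col * dpp
  y <- -g$row * dpp
  r <- sqrt(x^2 + y^2)
  env <- probe_envelope_r(r, spec$flat_diam, spec$skirt_sd)
  thetas <- channel_orientations(congruent_theta)
  C <- S <- matrix(0, side * side, 16)
  for (k in 1:16) {
    arg <- 2 * pi * spec$carrier_freq *
      (x * cos(thetas[k]) + y * sin(thetas[k]))
    C[, k] <- as.vector(cos(arg) * env)
    S[, k] <- as.vector(sin(arg) * env)
  }
  list(basis = cbind(C, S), envelope = env, side = side)
}

#' Render the probe patch
#'
#' Sums 16 cosine-carrier Gabor wavelets sharing one compound envelope
#' (flat disc of diameter \code{flat_diam} with a Gaussian skirt), one per
#' orientation channel, with contrasts \code{s} and random phases drawn
#' deterministically from \code{spec$phase_seed}.
#'
#' @param spec a [probe_spec].
#' @param s 16-entry contrast vector (signal + noise).
#' @param congruent_theta congruent orientation, radians.
#' @param geometry a [scene_geometry] (sets the degree/pixel calibration).
#' @return object of class \code{probe_patch}: \code{patch} (2-D contrast
#'   array), \code{envelope}, \code{phases}, \code{s}.
#' @export
render_probe <- function(spec, s, congruent_theta, geometry) {
  if (length(s) != 16) sp_input_error("s must have 16 entries")
  side <- probe_patch_side(spec, geometry)
  if (side > min(geometry$height_px, geometry$width_px))
    sp_input_error("probe patch larger than scene")
  phases <- with_seed(spec$phase_seed, stats::runif(16, 0, 2 * pi))
  pb <- probe_carrier_basis(spec, congruent_theta, geometry, side)
  a <- c(s * cos(phases), -s * sin(phases))
  patch <- matrix(pb$basis %*% a, side, side)
  structure(list(patch = patch, envelope = pb$envelope, phases = phases,
                 s = s, side = side, spec = spec,
                 congruent_theta = congruent_theta),
            class = "probe_patch")
}

#' Graft a probe patch into a scene
#'
#' Blends the probe into the scene under the probe envelope:
#' \code{out = env * bg * (1 + patch) + (1 - env) * scene}, where bg is the
#' background luminance, then clips to the admissible luminance range.
#'
#' @param scene a [gray_image].
#' @param patch a \code{probe_patch} from [render_probe()].
#' @param point insertion point: an \code{insertion_point} or length-2
#'   (row, col), 0-based center.
#' @return a [gray_image] (not re-normalized).
#' @export
graft_probe <- function(scene, patch, point) {
  if (inherits(point, "insertion_point")) point <- c(point$row, point$col)
  geom <- scene$geometry
  h <- (patch$side - 1) / 2
  r0 <- point[1] - h; r1 <- point[1] + h
  c0 <- point[2] - h; c1 <- point[2] + h
  if (r0 < 0 || c0 < 0 || r1 > geom$height_px - 1 || c1 > geom$width_px - 1)
    sp_input_error("probe insertion out of scene bounds")
  v <- scene$values
  sub <- v[(r0:r1) + 1, (c0:c1) + 1]
  env <- patch$envelope
  bg <- geom$background_lum
  blended <- env * (bg * (1 + patch$patch)) + (1 - env) * sub
  v[(r0:r1) + 1, (c0:c1) + 1] <- blended
  out <- scene
  out$values <- clip_lum(v, geom)
  out
}

## radial spatial-frequency grid in cycles/degree for an FFT of this shape
freq_grid_cpd <- function(nr, nc, deg_per_px) {
  fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[1:nr] / nr
  fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[1:nc] / nc
  f2 <- outer(fr^2, fc^2, "+")
  sqrt(f2) / deg_per_px
}

## blend `modified` back towards `orig` inside a tapered disc around `point`
preserve_probe_region <- function(orig, modified, point, geometry,
                                  preserve_diam = 3.1, taper_deg = 0.25) {
  if (is.null(point)) return(modified)
  if (inherits(point, "insertion_point")) point <- c(point$row, point$col)
  r <- dist_from_point(nrow(orig), ncol(orig), point) * geometry$deg_per_px
  env <- raised_cosine_taper(r, preserve_diam / 2, taper_deg)
  env * orig + (1 - env) * modified
}

#' Lowpass or highpass filter a scene
#'
#' Lowpass: power uniformly attenuated by 70 percent (amplitude times
#' sqrt(0.3)) for all frequencies above 0.5 cycles/degree. Highpass: power
#' attenuation ramps log-linearly in frequency from 10 percent at 7
#' cycles/degree to 100 percent at and below 0.5 cycles/degree; frequencies
#' above 7 are untouched. The DC component (mean luminance) is preserved in
#' both modes. A tapered circular region of diameter \code{preserve_diam}
#' around \code{probe_point} is left intact (pass \code{probe_point = NULL}
#' to filter the whole image).
#'
#' @param scene a [gray_image].
#' @param mode "lowpass" or "highpass".
#' @param probe_point (row, col) 0-based, an \code{insertion_point}, or NULL.
#' @param preserve_diam intact-region diameter, degrees (3.1).
#' @return a [gray_image].
#' @export
filter_scene <- function(scene, mode = c("lowpass", "highpass"),
                         probe_point = NULL, preserve_diam = 3.1) {
  mode <- match.arg(mode)
  geom <- scene$geometry
  v <- scene$values
  f <- freq_grid_cpd(nrow(v), ncol(v), geom$deg_per_px)
  if (mode == "lowpass") {
    amp <- ifelse(f > 0.5, sqrt(0.3), 1)
  } else {
    pow_atten <- matrix(0, nrow(f), ncol(f))
    low <- f <= 0.5 & f > 0
    mid <- f > 0.5 & f < 7
    pow_atten[low] <- 1
    pow_atten[mid] <- 1 + (0.1 - 1) * (log(f[mid] / 0.5) / log(7 / 0.5))
    amp <- sqrt(1 - pow_atten)
  }
  amp[1, 1] <- 1  # keep mean luminance
  filt <- Re(stats::fft(stats::fft(v) * amp, inverse = TRUE)) / length(v)
  out <- preserve_probe_region(v, filt, probe_point, geom, preserve_diam)
  res <- scene
  res$values <- clip_lum(out, geom)
  res
}

#' Warp a scene (swirl/lens distortions)
#'
#' Forty lattice points uniformly span the scene; those within
#' \code{exclude_deg} of the probe are dropped. Each remaining center is
#' randomly assigned a swirl (local rotation by an angle falling off with a
#' Gaussian window of the distance from the center) or a lens (exponential
#' radial distortion of local coordinates under the same window). The window
#' SD is 0.6 degrees for weak and 1.2 for strong warping. Displacements are
#' suppressed within \code{exclude_deg} of the probe so that region is
#' unwarped. Deterministic given \code{seed}.
#'
#' @param scene a [gray_image].
#' @param probe_point (row, col) 0-based or \code{insertion_point}.
#' @param strength "weak" or "strong".
#' @param seed integer RNG seed.
#' @param swirl_peak peak swirl rotation, radians (0.5).
#' @param lens_exponent peak lens magnification factor (1.5).
#' @param n_centers number of lattice points (40).
#' @param exclude_deg probe protection radius, degrees (3.2).
#' @param centers optional data.frame (row, col; 0-based) overriding the
#'   lattice, e.g. for controlled single-center distortions.
#' @param kinds optional character vector ("swirl"/"lens") overriding the
#'   random per-center choice; recycled signs of +1 apply.
#' @return a [gray_image].
#' @export
warp_scene <- function(scene, probe_point, strength = c("weak", "strong"),
                       seed = 1L, swirl_peak = 0.5, lens_exponent = 1.5,
                       n_centers = 40, exclude_deg = 3.2, centers = NULL,
                       kinds = NULL) {
  strength <- match.arg(strength)
  if (inherits(probe_point, "insertion_point"))
    probe_point <- c(probe_point$row, probe_point$col)
  geom <- scene$geometry
  sd_deg <- if (strength == "weak") 0.6 else 1.2
  sd_px <- deg2px(sd_deg, geom)
  nr <- nrow(scene$values); nc <- ncol(scene$values)

  if (is.null(centers)) {
    ## lattice spanning the scene, aspect-matched so rows*cols ~ n_centers
    grows <- max(2, round(sqrt(n_centers * nr / nc)))
    gcols <- max(2, round(n_centers / grows))
    cr <- (seq_len(grows) - 0.5) / grows * (nr - 1)
    cc <- (seq_len(gcols) - 0.5) / gcols * (nc - 1)
    centers <- expand.grid(row = cr, col = cc)
  }
  dprobe <- sqrt((centers$row - probe_point[1])^2 +
                 (centers$col - probe_point[2])^2)
  centers <- centers[dprobe > deg2px(exclude_deg, geom), ]

  g <- coord_grids(nr, nc)
  disp_r <- matrix(0, nr, nc); disp_c <- matrix(0, nr, nc)
  if (sd_px > 0 && nrow(centers) > 0) {
    modes <- if (is.null(kinds)) {
      with_seed(seed, list(
        kind = sample(c("swirl", "lens"), nrow(centers), replace = TRUE),
        sign = sample(c(-1, 1), nrow(centers), replace = TRUE)))
    } else {
      list(kind = rep(kinds, length.out = nrow(centers)),
           sign = rep(1, nrow(centers)))
    }
    for (i in seq_len(nrow(centers))) {
      dr <- g$row - centers$row[i]
      dc <- g$col - centers$col[i]
      r2 <- dr^2 + dc^2
      w <- exp(-r2 / (2 * sd_px^2))
      if (modes$kind[i] == "swirl") {
        ang <- modes$sign[i] * swirl_peak * w
        src_r <- cos(ang) * dr - sin(ang) * dc
        src_c <- sin(ang) * dr + cos(ang) * dc
      } else {
        fac <- exp(log(lens_exponent) * w)
        src_r <- dr * fac
        src_c <- dc * fac
      }
      disp_r <- disp_r + (src_r - dr)
      disp_c <- disp_c + (src_c - dc)
    }
  }
  ## suppress displacement near the probe so that region stays unwarped
  rp <- dist_from_point(nr, nc, probe_point) * geom$deg_per_px
  keep <- 1 - raised_cosine_taper(rp, exclude_deg, 0.25)
  disp_r <- disp_r * keep
  disp_c <- disp_c * keep
  if (max(abs(disp_r)) == 0 && max(abs(disp_c)) == 0) return(scene)

  out <- scene
  out$values <- bilinear_remap(scene$values, g$row + disp_r, g$col + disp_c)
  out$values <- clip_lum(out$values, geom)
  out
}

## bilinear sampling at (row, col) source coordinates (0-based), replicate
## border
bilinear_remap <- function(v, src_r, src_c) {
  nr <- nrow(v); nc <- ncol(v)
  src_r <- pmin(pmax(src_r, 0), nr - 1)
  src_c <- pmin(pmax(src_c, 0), nc - 1)
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  idx <- function(r, c) v[cbind(as.vector(r) + 1, as.vector(c) + 1)]
  out <- (1 - fr) * (1 - fc) * idx(r0, c0) + (1 - fr) * fc * idx(r0, c1) +
         fr * (1 - fc) * idx(r1, c0) + fr * fc * idx(r1, c1)
  matrix(out, nr, nc)
}

#' Cut-out and lines manipulations
#'
#' The thickened top-down map is thresholded (> 0) to a binary boundary
#' mask. In "lines" mode, boundary pixels are set to the maximum luminance
#' (60 cd/m2) on the otherwise unchanged scene. In "cutout" mode, every
#' connected region delimited by the boundaries is filled with a constant
#' luminance drawn without replacement from a set uniformly spanning the
#' luminance range (so no two regions share a value); boundary pixels take
#' the value of the nearest region. The permutation is fixed by \code{seed}.
#'
#' @param scene a [gray_image].
#' @param annotations list of binary annotator masks (thickened internally),
#'   or a precomputed top-down map passed via \code{top_down}.
#' @param mode "cutout" or "lines".
#' @param seed integer seed for the luminance permutation.
#' @param top_down optional precomputed top-down map (overrides
#'   \code{annotations}).
#' @return a [gray_image].
#' @export
cutout_or_lines <- function(scene, annotations = NULL,
                            mode = c("cutout", "lines"), seed = 1L,
                            top_down = NULL) {
  mode <- match.arg(mode)
  geom <- scene$geometry
  if (is.null(top_down)) {
    if (is.null(annotations)) sp_input_error("need annotations or top_down")
    top_down <- build_top_down_map(annotations, geom)
  }
  boundary <- top_down > 0
  out <- scene
  if (mode == "lines") {
    v <- scene$values
    v[boundary] <- geom$lum_range[2]
    out$values <- v
    return(out)
  }
  lab <- EBImage::bwlabel((!boundary) + 0)
  R <- max(lab)
  if (R < 1) sp_input_error("no regions delimited by boundaries")
  vals <- seq(geom$lum_range[1], geom$lum_range[2], length.out = max(R, 2))
  vals <- with_seed(seed, sample(vals, R))
  ## propagate region labels across boundary pixels (nearest region wins)
  lab <- matrix(as.numeric(lab), nrow(lab), ncol(lab))
  while (any(lab == 0)) {
    grown <- EBImage::dilate(lab, EBImage::makeBrush(3, "box"))
    fill <- lab == 0 & grown > 0
    if (!any(fill)) break
    lab[fill] <- grown[fill]
  }
  out$values <- matrix(vals[lab], nrow(lab), ncol(lab))
  out
}

#' Phase or power scrambling
#'
#' A white-noise image is generated (seeded); "power_only" keeps the scene's
#' power spectrum and takes the noise phase spectrum, "phase_only" keeps the
#' scene's phase spectrum and takes the noise power spectrum. The DC
#' component is kept from the scene so mean luminance is preserved, and
#' Hermitian symmetry guarantees a real image. The tapered probe region is
#' preserved as in [filter_scene()] unless \code{probe_point} is NULL.
#'
#' @param scene a [gray_image].
#' @param mode "power_only" or "phase_only".
#' @param probe_point (row, col) 0-based, \code{insertion_point}, or NULL.
#' @param seed integer seed for the white-noise image.
#' @param clip clip the result to the display luminance range (default
#'   TRUE; phase-only images are whitened and can exceed the range, in
#'   which case clipping perturbs the spectrum slightly).
#' @return a [gray_image].
#' @export
scramble_scene <- function(scene, mode = c("power_only", "phase_only"),
                           probe_point = NULL, seed = 1L, clip = TRUE) {
  mode <- match.arg(mode)
  geom <- scene$geometry
  v <- scene$values
  noise <- with_seed(seed, matrix(stats::runif(length(v), geom$lum_range[1],
                                               geom$lum_range[2]),
                                  nrow(v), ncol(v)))
  Fs <- stats::fft(v)
  Fn <- stats::fft(noise)
  comb <- if (mode == "power_only") {
    Mod(Fs) * exp(1i * Arg(Fn))
  } else {
    ## replacement power spectrum rescaled to the scene's contrast energy so
    ## phase-only scenes keep a comparable luminance excursion
    A <- Mod(Fn)
    scale <- sqrt((sum(Mod(Fs)^2) - Mod(Fs[1, 1])^2) /
                  max(sum(A^2) - A[1, 1]^2, .Machine$double.eps))
    (A * scale) * exp(1i * Arg(Fs))
  }
  comb[1, 1] <- Fs[1, 1]
  scr <- Re(stats::fft(comb, inverse = TRUE)) / length(v)
  out <- preserve_probe_region(v, scr, probe_point, geom)
  res <- scene
  res$values <- if (clip) clip_lum(out, geom) else out
  res
}

#' Gap stimulus
#'
#' Surrounds the probe with a circular mean-luminance annulus extending from
#' the probe edge out to \code{gap_diam_multiple} probe diameters, smoothly
#' merging into the scene via a raised-cosine outer taper. A multiple of 1
#' leaves the stimulus untouched.
#'
#' @param scene_with_probe a [gray_image] containing the grafted probe.
#' @param probe_point (row, col) 0-based or \code{insertion_point}.
#' @param gap_diam_multiple gap diameter in units of probe diameter (>= 1).
#' @param probe_diam probe (flat-envelope) diameter, degrees (1.6).
#' @param taper_deg outer taper width, degrees (0.25).
#' @return a [gray_image].
#' @export
gap_stimulus <- function(scene_with_probe, probe_point, gap_diam_multiple,
                         probe_diam = 1.6, taper_deg = 0.25) {
  if (gap_diam_multiple < 1) sp_input_error("gap_diam_multiple must be >= 1")
  if (inherits(probe_point, "insertion_point"))
    probe_point <- c(probe_point$row, probe_point$col)
  geom <- scene_with_probe$geometry
  nr <- nrow(scene_with_probe$values); nc <- ncol(scene_with_probe$values)
  r_probe <- probe_diam / 2
  r_gap <- gap_diam_multiple * r_probe
  edge_dist <- min(probe_point[1], probe_point[2],
                   nr - 1 - probe_point[1], nc - 1 - probe_point[2]) *
    geom$deg_per_px
  if (r_gap + taper_deg > edge_dist)
    sp_input_error("gap extends beyond image bounds")
  if (gap_diam_multiple == 1) return(scene_with_probe)
  r <- dist_from_point(nr, nc, probe_point) * geom$deg_per_px
  w <- raised_cosine_taper(r, r_gap - taper_deg, taper_deg)
  w[r <= r_probe] <- 0
  out <- scene_with_probe
  out$values <- (1 - w) * scene_with_probe$values + w * geom$background_lum
  out
}
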