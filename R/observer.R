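## -------------------------------------------------------------------------
## Model observers: quadrature-pair gain-control model with Poor/Rich
## filter states, and a channel-domain linear-template SDT observer.
## -------------------------------------------------------------------------

#' Default model-patch geometry
#'
#' Standalone calibration for rendering probe patches outside a scene
#' (model-observer simulations).
#'
#' @param px_per_deg pixels per degree (default 16, i.e. 16 samples per
#'   carrier cycle at 1 cycle/degree).
#' @param spec a [probe_spec] used to size the patch.
#' @return a [scene_geometry] covering one probe patch.
#' @export
model_patch_geometry <- function(px_per_deg = 16, spec = probe_spec()) {
  dpp <- 1 / px_per_deg
  side <- spec$flat_diam + 8 * spec$skirt_sd
  n <- ceiling(side / dpp)
  if (n %% 2 == 0) n <- n + 1
  scene_geometry(n, n, deg_per_px = dpp)
}

#' Gabor filter
#'
#' Cosine- (even) or sine-carrier (odd) Gabor with an anisotropic Gaussian
#' envelope; \code{sigma_par} extends along the bar (constant-phase) axis
#' and sets orientation tuning width, \code{sigma_perp} along the wave
#' vector.
#'
#' @param theta orientation, radians CCW from the x-axis.
#' @param freq carrier spatial frequency, cycles/degree.
#' @param sigma_par,sigma_perp envelope SDs, degrees.
#' @param phase 0 (even) or 1 (odd).
#' @param geometry a [scene_geometry] defining the sampling grid.
#' @return numeric matrix (height x width of the geometry).
#' @export
gabor_filter <- function(theta, freq, sigma_par, sigma_perp, phase = 0,
                         geometry = model_patch_geometry()) {
  nr <- geometry$height_px; nc <- geometry$width_px
  h <- c((nr - 1) / 2, (nc - 1) / 2)
  g <- coord_grids(nr, nc, center = h)
  x <- g$col * geometry$deg_per_px
  y <- -g$row * geometry$deg_per_px
  u <- x * cos(theta) + y * sin(theta)      # along wave vector
  v <- -x * sin(theta) + y * cos(theta)     # along the bar
  env <- exp(-u^2 / (2 * sigma_perp^2) - v^2 / (2 * sigma_par^2))
  carrier <- if (phase == 0) cos(2 * pi * freq * u) else sin(2 * pi * freq * u)
  env * carrier
}

#' Quadrature-pair energy
#'
#' Sum of squared Frobenius inner products of the patch with the even and
#' odd Gabor filters at orientation \code{theta}. The broadness multiple
#' scales the filter so its tuning is \code{broadness} times wider than the
#' signal-matched filter: in "bandwidth" mode the Gaussian envelope SD is
#' divided by the multiple (isotropically, so orientation and frequency
#' tuning broaden together and a large multiple is genuinely untuned); in
#' "frequency" mode the filter's carrier frequency is multiplied by it
#' instead (a spatial-frequency mismatch reading).
#'
#' @param patch 2-D numeric matrix (contrast units), or a
#'   \code{probe_patch}.
#' @param theta filter orientation, radians.
#' @param broadness broadness multiple f (>= 1).
#' @param geometry sampling geometry of the patch.
#' @param freq signal carrier frequency, cycles/degree.
#' @param sigma0 signal-matched envelope SD, degrees.
#' @param broadness_mode "bandwidth" or "frequency".
#' @return scalar energy >= 0.
#' @export
quadrature_energy <- function(patch, theta, broadness = 1,
                              geometry = model_patch_geometry(),
                              freq = 1, sigma0 = 0.4,
                              broadness_mode = c("bandwidth", "frequency")) {
  broadness_mode <- match.arg(broadness_mode)
  if (inherits(patch, "probe_patch")) patch <- patch$patch
  W <- quadrature_pair(theta, broadness, geometry, freq, sigma0,
                       broadness_mode)
  sum(patch * W$even)^2 + sum(patch * W$odd)^2
}

quadrature_pair <- function(theta, broadness, geometry, freq, sigma0,
                            broadness_mode) {
  if (broadness_mode == "bandwidth") {
    ## isotropic envelope shrink: both the orientation and the frequency
    ## tuning routes broaden together by the multiple, so a large multiple
    ## yields a genuinely untuned operator
    s <- sigma0 / broadness
    even <- gabor_filter(theta, freq, s, s, 0, geometry)
    odd  <- gabor_filter(theta, freq, s, s, 1, geometry)
  } else {
    even <- gabor_filter(theta, freq * broadness, sigma0, sigma0, 0, geometry)
    odd  <- gabor_filter(theta, freq * broadness, sigma0, sigma0, 1, geometry)
  }
  list(even = even, odd = odd)
}

#' Observer state for the gain-control model
#'
#' @param state_label "Rich" or "Poor". Defaults for the broadness
#'   multiples follow the state: Rich has f_cong = 1, f_incong = 3
#'   (congruent filter matched to the signal, incongruent mildly tuned);
#'   Poor has f_cong = 4, f_incong = 21 (mildly tuned / virtually untuned).
#' @param f_cong,f_incong broadness multiples (>= 1) of the congruent and
#'   incongruent filters.
#' @param internal_noise_sd late additive internal noise SD applied to the
#'   decision variable.
#' @param criterion decision threshold on the decision variable, or NA until
#'   calibrated via [calibrate_criterion()].
#' @param broadness_mode see [quadrature_energy()].
#' @return object of class \code{observer_state}.
#' @export
observer_state <- function(state_label = c("Rich", "Poor"),
                           f_cong = NULL, f_incong = NULL,
                           internal_noise_sd = 0, criterion = NA_real_,
                           broadness_mode = c("bandwidth", "frequency")) {
  state_label <- match.arg(state_label)
  broadness_mode <- match.arg(broadness_mode)
  if (is.null(f_cong)) f_cong <- if (state_label == "Rich") 1 else 4
  if (is.null(f_incong)) f_incong <- if (state_label == "Rich") 3 else 21
  if (f_cong < 1 || f_incong < 1) sp_input_error("broadness multiples must be >= 1")
  if (internal_noise_sd < 0) sp_input_error("internal noise SD must be >= 0")
  structure(list(state_label = state_label, f_cong = f_cong,
                 f_incong = f_incong, internal_noise_sd = internal_noise_sd,
                 criterion = criterion, broadness_mode = broadness_mode),
            class = "observer_state")
}

#' @export
print.observer_state <- function(x, ...) {
  cat(sprintf("<observer_state> %s: f_cong=%g f_incong=%g sigma_int=%g criterion=%s\n",
              x$state_label, x$f_cong, x$f_incong, x$internal_noise_sd,
              ifelse(is.na(x$criterion), "uncalibrated",
                     sprintf("%.4f", x$criterion))))
  invisible(x)
}

## Precompute the 32 x 4 projection of the channel carrier basis onto the
## four model filters (even/odd x congruent/incongruent). All per-trial
## computation then reduces to 32-vector algebra: a rendered patch is
## B %*% a with a = c(s*cos(phi), -s*sin(phi)), so <patch, W> = (U' a).
gain_control_projection <- function(state, spec, congruent_theta, geometry,
                                    freq = NULL, sigma0 = 0.4) {
  if (is.null(freq)) freq <- spec$carrier_freq
  pb <- probe_carrier_basis(spec, congruent_theta, geometry)
  th <- channel_orientations(congruent_theta)
  Wc <- quadrature_pair(th[5], state$f_cong, geometry, freq, sigma0,
                        state$broadness_mode)
  Wi <- quadrature_pair(th[13], state$f_incong, geometry, freq, sigma0,
                        state$broadness_mode)
  U <- crossprod(pb$basis, cbind(as.vector(Wc$even), as.vector(Wc$odd),
                                 as.vector(Wi$even), as.vector(Wi$odd)))
  list(U = U, basis = pb$basis)
}

## vectorized trial engine shared by calibration and simulation
gain_control_batch <- function(state, spec, q, noise, phases, U) {
  n <- length(q)
  s <- noise
  s[q == 1, 5] <- s[q == 1, 5] + spec$rho
  s[q == 0, 13] <- s[q == 0, 13] + spec$rho
  A <- cbind(s * cos(phases), -s * sin(phases))
  R <- A %*% U
  r1 <- R[, 1]^2 + R[, 2]^2
  r0 <- R[, 3]^2 + R[, 4]^2
  tot <- r1 + r0
  if (any(tot == 0)) sp_undefined_value("degenerate stimulus: zero energy")
  list(dv = r1 / tot, r1 = r1, r0 = r0, s = s)
}

#' Simulate gain-control model trials
#'
#' Renders probe stimuli in the channel/carrier domain (mathematically
#' identical to rendering the 2-D patch and taking Frobenius products, by
#' linearity), computes the normalized decision variable
#' r1 / (r1 + r0), optionally adds late Gaussian internal noise, and
#' thresholds at the state's criterion.
#'
#' @param state an [observer_state] (criterion may be NA if
#'   \code{calibrate} is TRUE).
#' @param spec a [probe_spec]; \code{spec$rho} is the signal intensity.
#' @param n_trials number of trials (half congruent, half incongruent).
#' @param congruent_theta congruent orientation, radians.
#' @param geometry sampling geometry ([model_patch_geometry()]).
#' @param seed RNG seed.
#' @param calibrate if TRUE and the criterion is NA, calibrate it first via
#'   [calibrate_criterion()].
#' @return data.frame with q, dv, response, z and noise columns n01..n16.
#' @export
simulate_gain_control <- function(state, spec, n_trials,
                                  congruent_theta = 0,
                                  geometry = model_patch_geometry(),
                                  seed = 1L, calibrate = TRUE) {
  if (is.na(state$criterion)) {
    if (!calibrate) sp_input_error("observer criterion is not calibrated")
    state <- calibrate_criterion(state, spec, congruent_theta = congruent_theta,
                                 geometry = geometry, seed = seed + 1L)
  }
  proj <- gain_control_projection(state, spec, congruent_theta, geometry)
  with_seed(seed, {
    q <- rep(c(1L, 0L), length.out = n_trials)
    noise <- matrix(stats::rnorm(n_trials * 16, spec$noise_mean,
                                 spec$noise_sd), n_trials, 16)
    lo <- spec$noise_mean - spec$clip_sd * spec$noise_sd
    hi <- spec$noise_mean + spec$clip_sd * spec$noise_sd
    noise <- pmin(pmax(noise, lo), hi)
    phases <- matrix(stats::runif(n_trials * 16, 0, 2 * pi), n_trials, 16)
    gb <- gain_control_batch(state, spec, q, noise, phases, proj$U)
    dv <- gb$dv
    if (state$internal_noise_sd > 0)
      dv <- dv + stats::rnorm(n_trials, 0, state$internal_noise_sd)
    resp <- ifelse(dv > state$criterion, "congruent", "incongruent")
    out <- data.frame(q = q, dv = gb$dv, response = resp,
                      z = as.integer((resp == "congruent") == (q == 1)))
    noise_df <- as.data.frame(noise)
    names(noise_df) <- sprintf("n%02d", 1:16)
    cbind(out, noise_df)
  })
}

#' Calibrate the decision criterion
#'
#' The unbiased criterion is the mean decision variable across
#' \code{n_trials} simulated trials, half containing a congruent and half an
#' incongruent signal.
#'
#' @inheritParams simulate_gain_control
#' @param n_trials calibration trials (default 8000).
#' @param return_log if TRUE, attach the per-trial decision variables as
#'   attribute \code{"dv_log"}.
#' @return the [observer_state] with \code{criterion} set.
#' @export
calibrate_criterion <- function(state, spec, n_trials = 8000,
                                congruent_theta = 0,
                                geometry = model_patch_geometry(),
                                seed = 1L, return_log = FALSE) {
  proj <- gain_control_projection(state, spec, congruent_theta, geometry)
  dv <- with_seed(seed, {
    q <- rep(c(1L, 0L), length.out = n_trials)
    noise <- matrix(stats::rnorm(n_trials * 16, spec$noise_mean,
                                 spec$noise_sd), n_trials, 16)
    lo <- spec$noise_mean - spec$clip_sd * spec$noise_sd
    hi <- spec$noise_mean + spec$clip_sd * spec$noise_sd
    noise <- pmin(pmax(noise, lo), hi)
    phases <- matrix(stats::runif(n_trials * 16, 0, 2 * pi), n_trials, 16)
    gain_control_batch(state, spec, q, noise, phases, proj$U)$dv
  })
  state$criterion <- mean(dv)
  if (return_log) attr(state, "dv_log") <- dv
  state
}

#' Single gain-control model trial
#'
#' Operates on an explicit 2-D stimulus patch via [quadrature_energy()];
#' the batch simulator [simulate_gain_control()] computes the identical
#' quantities in the carrier basis.
#'
#' @param stimulus_patch 2-D contrast matrix or \code{probe_patch}.
#' @param state an [observer_state] with a calibrated criterion.
#' @param congruent_theta congruent orientation, radians.
#' @param geometry sampling geometry of the patch.
#' @param sigma0 signal-matched filter envelope SD, degrees.
#' @return list with r_cong, r_incong, dv, response.
#' @export
model_trial <- function(stimulus_patch, state, congruent_theta = 0,
                        geometry = model_patch_geometry(), sigma0 = 0.4) {
  if (is.na(state$criterion)) sp_input_error("criterion not calibrated")
  if (inherits(stimulus_patch, "probe_patch")) {
    congruent_theta <- stimulus_patch$congruent_theta
    stimulus_patch <- stimulus_patch$patch
  }
  th <- channel_orientations(congruent_theta)
  r1 <- quadrature_energy(stimulus_patch, th[5], state$f_cong, geometry,
                          sigma0 = sigma0,
                          broadness_mode = state$broadness_mode)
  r0 <- quadrature_energy(stimulus_patch, th[13], state$f_incong, geometry,
                          sigma0 = sigma0,
                          broadness_mode = state$broadness_mode)
  if (r1 + r0 == 0) sp_undefined_value("degenerate stimulus: zero energy")
  dv <- r1 / (r1 + r0)
  dv_noisy <- dv
  if (state$internal_noise_sd > 0)
    dv_noisy <- dv + stats::rnorm(1, 0, state$internal_noise_sd)
  list(r_cong = r1, r_incong = r0, dv = dv,
       response = if (dv_noisy > state$criterion) "congruent" else "incongruent")
}

#' Linear-template observer trial
#'
#' Channel-domain SDT observer: decision variable
#' \code{sum(template * s) + sigma_int * z} with z standard normal; responds
#' congruent when above \code{criterion}. This is the fast surrogate used
#' for large-N psychometric simulations.
#'
#' @param s 16-entry stimulus contrast vector.
#' @param template 16-entry weight vector.
#' @param sigma_int internal noise SD (decision-variable units).
#' @param criterion decision threshold.
#' @return "congruent" or "incongruent".
#' @export
template_observer_trial <- function(s, template, sigma_int = 0,
                                    criterion = 0) {
  if (!all(is.finite(template))) sp_input_error("template must be finite")
  dv <- sum(template * s) + if (sigma_int > 0) stats::rnorm(1, 0, sigma_int) else 0
  if (dv > criterion) "congruent" else "incongruent"
}
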