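test_that("target vectors put rho on the congruent or incongruent channel", {
  t1 <- make_target(1, 0.12)
  expect_equal(t1[5], 0.12)
  expect_equal(sum(t1 != 0), 1)
  t0 <- make_target(0, 0.12)
  expect_equal(t0[13], 0.12)
  expect_equal(sum(t0 != 0), 1)
  expect_equal(make_target(1, 0), numeric(16))
  expect_error(make_target(2, 0.1), class = "sceneprobe_input_error")
})

test_that("orientation noise is clipped Gaussian with the stated moments", {
  spec <- probe_spec()
  set.seed(4)
  draws <- replicate(200, sample_noise(spec))
  expect_true(all(draws >= 0.03 - 4 * 0.007 - 1e-12))
  expect_true(all(draws <= 0.03 + 4 * 0.007 + 1e-12))

  spec0 <- probe_spec(noise_sd = 0)
  expect_equal(sample_noise(spec0), rep(0.03, 16))

  set.seed(7)
  big <- matrix(stats::rnorm(1e5 * 16, 0.03, 0.007), ncol = 16)
  big <- pmin(pmax(big, 0.03 - 4 * 0.007), 0.03 + 4 * 0.007)
  expect_lt(abs(mean(big) - 0.03), 1e-4)
})

test_that("probe rendering is a deterministic enveloped Gabor sum", {
  spec <- probe_spec(phase_seed = 9)
  geom <- model_patch_geometry()
  z <- render_probe(spec, numeric(16), 0.3, geom)
  expect_equal(max(abs(z$patch)), 0)

  ## single active channel equals a directly evaluated enveloped Gabor
  s <- numeric(16); s[7] <- 0.05
  p <- render_probe(spec, s, 0.3, geom)
  side <- p$side; h <- (side - 1) / 2
  x <- outer(rep(1, side), (0:(side - 1) - h)) * geom$deg_per_px
  y <- -outer((0:(side - 1) - h), rep(1, side)) * geom$deg_per_px
  th <- (0.3 + (7 - 5) * pi / 16) %% pi
  r <- sqrt(x^2 + y^2)
  env <- ifelse(r <= 0.8, 1, exp(-(r - 0.8)^2 / (2 * 0.1^2)))
  direct <- 0.05 * cos(2 * pi * (x * cos(th) + y * sin(th)) + p$phases[7]) * env
  expect_lt(max(abs(p$patch - direct)), 1e-12)

  expect_identical(render_probe(spec, s, 0.3, geom)$patch, p$patch)
})

test_that("probe grafting blends under the envelope and preserves the rest", {
  sc <- make_test_scene(3)
  spec <- probe_spec()
  geom <- sc$geometry
  pt <- c(48, 64)
  patch <- render_probe(spec, numeric(16), 0, geom)
  out <- graft_probe(sc, patch, pt)
  ## envelope = 1 at the center with zero contrast -> background luminance
  expect_equal(out$values[pt[1] + 1, pt[2] + 1], 32)
  ## far corner untouched (outside patch footprint)
  expect_equal(out$values[1, 1], sc$values[1, 1])

  ## scalar blend formula at an interior skirt pixel
  s <- numeric(16); s[5] <- 0.1
  p2 <- render_probe(spec, s, 0, geom)
  out2 <- graft_probe(sc, p2, pt)
  h <- (p2$side - 1) / 2
  i <- 4; j <- 11  # patch-local indices
  env <- p2$envelope[i, j]
  expect_gt(env, 0); expect_lt(env, 1)
  sr <- pt[1] - h + i - 1; sc_ <- pt[2] - h + j - 1
  manual <- env * 32 * (1 + p2$patch[i, j]) + (1 - env) * sc$values[sr + 1, sc_ + 1]
  expect_equal(out2$values[sr + 1, sc_ + 1], manual, tolerance = 1e-12)

  expect_error(graft_probe(sc, p2, c(2, 2)), class = "sceneprobe_input_error")
})

test_that("spectral filtering attenuates the stated bands and spares the probe disc", {
  ## pure grating at ~1 cpd on a 128 x 128 scene (12.8 deg at 0.1 deg/px)
  n <- 128
  geom <- scene_geometry(n, n, deg_per_px = 0.1)
  x <- outer(rep(1, n), 0:(n - 1)) * 0.1
  k <- 13  # cycles across the image -> 13 / 12.8 = 1.016 cpd
  v <- 32 + 3 * cos(2 * pi * k / (n * 0.1) * x)
  sc <- gray_image(v, geom, normalize = FALSE)
  lp <- filter_scene(sc, "lowpass", probe_point = NULL)
  amp_at <- function(img, k) Mod(stats::fft(img)[1, k + 1]) / length(img)
  ratio <- amp_at(lp$values, k) / amp_at(sc$values, k)
  expect_equal(ratio, sqrt(0.3), tolerance = 0.01)
  ## DC (mean luminance) unchanged
  expect_equal(mean(lp$values), mean(sc$values), tolerance = 1e-9)

  ## preserved disc: pixels within 1.4 deg of the probe point unchanged
  sc2 <- make_test_scene(6, 128, 128)
  pt <- c(64, 64)
  r <- sceneprobe:::dist_from_point(128, 128, pt) * sc2$geometry$deg_per_px
  for (mode in c("lowpass", "highpass")) {
    f <- filter_scene(sc2, mode, probe_point = pt)
    rel <- abs(f$values - sc2$values) / abs(sc2$values)
    expect_lt(max(rel[r <= 1.4]), 1e-6)
  }
  ## highpass removes low frequencies almost entirely
  hp <- filter_scene(sc2, "highpass", probe_point = NULL)
  Fin <- Mod(stats::fft(sc2$values)); Fout <- Mod(stats::fft(hp$values))
  fgrid <- sceneprobe:::freq_grid_cpd(128, 128, sc2$geometry$deg_per_px)
  low <- fgrid > 0 & fgrid <= 0.5
  expect_lt(max(Fout[low]), 1e-6 * max(Fin))
})

test_that("warping is identity at zero strength and spares the probe region", {
  sc <- make_test_scene(9)
  pt <- c(48, 64)
  same <- warp_scene(sc, pt, "weak", seed = 2, swirl_peak = 0,
                     lens_exponent = 1)
  expect_identical(same$values, sc$values)

  w <- warp_scene(sc, pt, "strong", seed = 2)
  r <- sceneprobe:::dist_from_point(96, 128, pt) * sc$geometry$deg_per_px
  expect_equal(w$values[r <= 3.2], sc$values[r <= 3.2])
  expect_gt(max(abs(w$values - sc$values)), 0.1)  # it does warp elsewhere
})

test_that("swirl displacement follows the analytic coordinate map", {
  ## ramp image: bilinear sampling of a linear function is exact, so each
  ## output pixel value equals the analytic source column coordinate
  nr <- 96; nc <- 128
  geom <- scene_geometry(nr, nc)
  ramp <- gray_image(matrix(rep(0:(nc - 1), each = nr) * 0.2 + 20, nr, nc),
                     geom, normalize = FALSE)
  ctr <- data.frame(row = 30, col = 40)
  pt <- c(80, 110)  # probe far from the swirl center
  out <- warp_scene(ramp, pt, "strong", centers = ctr, kinds = "swirl",
                    swirl_peak = 0.4)
  sd_px <- 1.2 / geom$deg_per_px
  for (px in list(c(30, 50), c(25, 35), c(38, 44))) {
    dr <- px[1] - ctr$row; dc <- px[2] - ctr$col
    wgt <- exp(-(dr^2 + dc^2) / (2 * sd_px^2))
    ang <- 0.4 * wgt
    src_c <- ctr$col + sin(ang) * dr + cos(ang) * dc
    got_c <- (out$values[px[1] + 1, px[2] + 1] - 20) / 0.2
    expect_lt(abs(got_c - src_c), 1e-9)
  }
})

test_that("cut-out assigns distinct region luminances; lines paint boundaries", {
  geom <- scene_geometry(60, 80)
  td <- matrix(0, 60, 80); td[30, ] <- 1; td[, 40] <- 0.5
  set.seed(2)
  sc <- gray_image(matrix(runif(60 * 80, 20, 44), 60, 80), geom,
                   normalize = FALSE)
  cut <- cutout_or_lines(sc, mode = "cutout", seed = 3, top_down = td)
  vals <- sort(unique(as.vector(cut$values)))
  expect_equal(length(vals), 4)  # 4 regions
  expect_true(all(vals >= 4 & vals <= 60))
  expect_true(all(vals %in% seq(4, 60, length.out = 4)))
  expect_equal(diff(vals), rep(diff(seq(4, 60, length.out = 4))[1], 3),
               tolerance = 1e-9)

  lines <- cutout_or_lines(sc, mode = "lines", seed = 3, top_down = td)
  expect_true(all(lines$values[td > 0] == 60))
  expect_equal(lines$values[td == 0], sc$values[td == 0])

  ## degenerate single region
  td0 <- matrix(0, 60, 80)
  one <- cutout_or_lines(sc, mode = "cutout", seed = 3, top_down = td0)
  expect_equal(length(unique(as.vector(one$values))), 1)
})

test_that("scrambling preserves the stated spectrum half and is seeded", {
  sc <- make_test_scene(11, 64, 64)
  po <- scramble_scene(sc, "power_only", probe_point = NULL, seed = 5)
  expect_equal(attr(po$values, "n_clipped"), 0)
  Pin <- Mod(stats::fft(sc$values))
  Pout <- Mod(stats::fft(po$values))
  nz <- Pin > 1e-9 * max(Pin)
  expect_lt(max(abs(Pout[nz] - Pin[nz]) / Pin[nz]), 1e-6)

  ## phase preservation is exact for the construction itself; clipping the
  ## whitened image to the display range would perturb it, so test unclipped
  ph <- scramble_scene(sc, "phase_only", probe_point = NULL, seed = 5,
                       clip = FALSE)
  Ain <- Arg(stats::fft(sc$values)); Aout <- Arg(stats::fft(ph$values))
  big <- Mod(stats::fft(ph$values)) > 1e-6 * max(Mod(stats::fft(ph$values)))
  dphi <- (Aout[big] - Ain[big] + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi[-1])), 1e-6)  # DC excluded (sign fixed separately)

  expect_identical(scramble_scene(sc, "power_only", NULL, seed = 5)$values,
                   po$values)
  ## probe disc preserved
  pt <- c(32, 32)
  pp <- scramble_scene(sc, "power_only", probe_point = pt, seed = 5)
  r <- sceneprobe:::dist_from_point(64, 64, pt) * sc$geometry$deg_per_px
  expect_equal(pp$values[r <= 1.4], sc$values[r <= 1.4], tolerance = 1e-9)
})

test_that("gap stimuli fill an annulus with background and taper into the scene", {
  sc <- make_test_scene(13, 128, 128)
  sc$geometry <- scene_geometry(128, 128, deg_per_px = 0.1)
  pt <- c(64, 64)
  g <- gap_stimulus(sc, pt, 2.5)
  r <- sceneprobe:::dist_from_point(128, 128, pt) * 0.1
  inner <- r > 0.85 & r < 2.5 * 0.8 - 0.25
  expect_true(all(g$values[inner] == 32))
  outer_px <- r > 2.5 * 0.8 + 0.01
  expect_equal(g$values[outer_px], sc$values[outer_px])

  expect_identical(gap_stimulus(sc, pt, 1)$values, sc$values)
  expect_error(gap_stimulus(sc, pt, 20), class = "sceneprobe_input_error")
})

test_that("rendered stimuli stay inside the luminance range", {
  sc <- make_test_scene(17)
  spec <- probe_spec(rho = 0.5)  # deliberately strong probe
  s <- make_target(1, 0.5) + 0.2
  p <- render_probe(spec, s, 0, sc$geometry)
  out <- graft_probe(sc, p, c(48, 64))
  expect_gte(min(out$values), 4)
  expect_lte(max(out$values), 60)
})
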