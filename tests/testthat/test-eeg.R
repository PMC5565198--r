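## small handmade datasets keep these tests fast and transparent

make_eeg <- function(waves, side, td = "rich", bu = "rich", subj = 1,
                     dist = 5) {
  n <- dim(waves)[3]
  erp_dataset(waves, data.frame(subject_id = rep(subj, length.out = n),
                                side = rep(side, length.out = n),
                                td_label = rep(td, length.out = n),
                                bu_label = rep(bu, length.out = n),
                                meridian_dist = rep(dist, length.out = n)))
}

test_that("preprocessing removes DC, suppresses 50 Hz, and rescales linearly", {
  lay <- electrode_layout()
  ne <- nrow(lay); nt <- 256
  w <- array(7, c(ne, nt, 4))
  ds <- make_eeg(w, c("left", "right"))
  out <- preprocess_erp(ds, "0.5/40", rescale_meridian = FALSE)
  expect_equal(max(abs(out$waveforms)), 0)

  t <- (0:(nt - 1)) / 256
  s50 <- sin(2 * pi * 50 * t)
  w2 <- array(rep(s50, each = ne), c(ne, nt, 4))
  ds2 <- make_eeg(w2, c("left", "right"))
  out2 <- preprocess_erp(ds2, "0.5/40", rescale_meridian = FALSE)
  expect_lt(sqrt(mean(out2$waveforms^2)) / sqrt(mean(w2^2)), 0.1)
  ## 10 Hz content passes nearly unattenuated
  s10 <- sin(2 * pi * 10 * t)
  w3 <- array(rep(s10, each = ne), c(ne, nt, 4))
  out3 <- preprocess_erp(make_eeg(w3, c("left", "right")), "0.5/40",
                         rescale_meridian = FALSE)
  expect_gt(sqrt(mean(out3$waveforms^2)) / sqrt(mean(w3^2)), 0.8)

  ## meridian rescaling is linear in the distance
  ds4 <- make_eeg(w3, c("left", "right"), dist = 2)
  ds8 <- make_eeg(w3, c("left", "right"), dist = 4)
  o4 <- preprocess_erp(ds4, "0.5/40")
  o8 <- preprocess_erp(ds8, "0.5/40")
  expect_equal(o8$waveforms, 2 * o4$waveforms, tolerance = 1e-12)
})

test_that("contra-minus-ipsi differencing is antisymmetric and recovers components", {
  lay <- electrode_layout()
  ne <- nrow(lay); nt <- 64
  ## identical left/right responses -> zero difference
  set.seed(81)
  base <- matrix(rnorm(ne * nt), ne, nt)
  w <- array(rep(base, 8), c(ne, nt, 8))
  ds <- make_eeg(w, c("left", "right"))
  cmi <- contra_minus_ipsi(ds)
  expect_lt(max(abs(cmi$diff)), 1e-10)

  ## inject a contralateral-only component on O1/O2
  comp <- sin(2 * pi * (0:(nt - 1)) / nt)
  w2 <- w
  iO1 <- which(lay$electrode == "O1"); iO2 <- which(lay$electrode == "O2")
  for (k in 1:8) {
    side <- c("left", "right")[(k %% 2) + 1]
    contra <- if (side == "left") iO2 else iO1
    w2[contra, , k] <- w2[contra, , k] + 3 * comp
  }
  meta_side <- c("left", "right")[(1:8 %% 2) + 1]
  ds2 <- make_eeg(w2, meta_side)
  cmi2 <- contra_minus_ipsi(ds2)
  expect_gte(cor(cmi2$diff["O1/O2", ], comp), 0.9)

  ## swapping all probe sides negates the difference
  ds3 <- make_eeg(w2, ifelse(meta_side == "left", "right", "left"))
  cmi3 <- contra_minus_ipsi(ds3)
  expect_equal(cmi3$diff, -cmi2$diff, tolerance = 1e-10)

  ## linearity without RMS normalization
  a <- contra_minus_ipsi(ds2, normalize_rms = FALSE)
  ds_sum <- ds2; ds_sum$waveforms <- 2 * ds2$waveforms
  b <- contra_minus_ipsi(ds_sum, normalize_rms = FALSE)
  expect_equal(b$diff, 2 * a$diff, tolerance = 1e-10)

  ## RMS normalization removes per-electrode gain scaling
  gains <- runif(ne, 0.5, 2)
  ds_g <- ds2; ds_g$waveforms <- ds2$waveforms * gains
  expect_equal(contra_minus_ipsi(ds_g)$diff, cmi2$diff, tolerance = 1e-10)
})

test_that("window pooling sums the selected rectangle exactly", {
  lay <- electrode_layout()
  pairs <- unique(lay$pair[!is.na(lay$pair)])
  np <- length(pairs); nt <- 100
  times <- -0.2 + (0:(nt - 1)) / 256
  per <- array(rnorm(3 * np * nt), c(3, np, nt),
               dimnames = list(NULL, pairs, NULL))
  map <- structure(list(values = apply(per, c(2, 3), mean), z = NULL,
                        per_subject = per, pairs = pairs, times = times,
                        subjects = 1:3, map_axis = "td"),
                   class = "modulation_map")
  occ <- unique(lay$pair[!is.na(lay$pair) & lay$group == "occipital"])
  got <- pool_window(map, "occipital", c(0, 0.1))
  manual <- numeric(3)
  for (s in 1:3) for (p in occ) for (ti in which(times >= 0 & times <= 0.1))
    manual[s] <- manual[s] + per[s, p, ti]
  expect_equal(got, manual, tolerance = 1e-12)

  zero <- map; zero$per_subject[] <- 0
  expect_equal(pool_window(zero, "occipital", c(0, 0.1)), rep(0, 3))
  ones <- map; ones$per_subject[] <- 1
  m_bins <- length(occ) * sum(times >= 0 & times <= 0.1)
  expect_equal(pool_window(ones, "occipital", c(0, 0.1)), rep(m_bins, 3))
  expect_error(pool_window(map, "occipital", c(5, 6)),
               class = "sceneprobe_input_error")
})

test_that("rich-poor modulation exposes an injected top-down effect only", {
  cfg <- erp_cohort_config(n_subjects = 7, trials_per_condition = 250)
  mm <- erp_cohort_modulation(cfg, c("td", "bu"), seed = 83)
  zp <- function(m) {
    p <- pool_window(m, "occipital", c(0, 0.1))
    mean(p) / (stats::sd(p) / sqrt(length(p)))
  }
  expect_gt(zp(mm$td), 2)
  expect_lt(abs(zp(mm$bu)), 2)

  ## ablation: removing the injected component nulls the modulation
  cfg0 <- erp_cohort_config(n_subjects = 7, trials_per_condition = 250,
                            td_mod_amp = 0)
  mm0 <- erp_cohort_modulation(cfg0, "td", seed = 83)
  expect_lt(abs(zp(mm0)), qt(0.999, df = 6))
  expect_lt(mean(abs(mm0$values)), mean(abs(mm$td$values)))
})

test_that("noiseless cohorts recover the injected component exactly", {
  ## lateral_amp = 0 so the rich-poor difference carries only the injected
  ## modulation (the lateral component's amplitude varies with the random
  ## per-trial meridian distance and would not cancel exactly)
  cfg <- erp_cohort_config(n_subjects = 2, trials_per_condition = 20,
                           noise_rms = 0, subject_gain_sd = 0,
                           lateral_amp = 0)
  ds <- generate_erp_cohort(cfg, seed = 85, subject = 1)
  lab <- ds$meta$td_label
  rich <- contra_minus_ipsi(ds, sel = lab == "rich", normalize_rms = FALSE)
  times <- ds$times
  mod_tc <- exp(-(times - 0.060)^2 / (2 * 0.025^2))
  ## occipital pair difference carries the modulation + lateral component;
  ## rich - poor isolates the modulation time course
  poor <- contra_minus_ipsi(ds, sel = lab == "poor", normalize_rms = FALSE)
  d <- rich$diff["O1/O2", ] - poor$diff["O1/O2", ]
  expect_gt(cor(d, mod_tc), 0.999)
})

test_that("full dataset and subject-by-subject modulation paths agree", {
  cfg <- erp_cohort_config(n_subjects = 3, trials_per_condition = 20)
  full <- generate_erp_cohort(cfg, seed = 87)
  full_pp <- preprocess_erp(full, "0.5/40")
  m1 <- rich_poor_modulation(full_pp, "td")
  m2 <- erp_cohort_modulation(cfg, "td", seed = 87)
  expect_equal(m1$values, m2$values, tolerance = 1e-10)
  expect_equal(m1$z, m2$z, tolerance = 1e-10)
})
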