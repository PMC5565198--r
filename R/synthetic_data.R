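## -------------------------------------------------------------------------
## Synthetic inputs: annotated scenes with orthogonal top-down/bottom-up
## structure, simulated psychophysical cohorts (incl. double-pass blocks),
## and synthetic lateralized ERP cohorts.
## -------------------------------------------------------------------------

#' Scene generator configuration
#'
#' Scenes are seeded random planar (Voronoi) tessellations of textured
#' regions. Each boundary between two regions independently receives a
#' top-down type (consensus: every simulated annotator marks it; weak:
#' marked with probability \code{p_weak}) and a bottom-up type (large or
#' small local luminance step), making the two map dimensions statistically
#' orthogonal by construction.
#'
#' @param height_px,width_px scene size in pixels (13 x 20 degrees at the
#'   default 0.1 deg/px).
#' @param n_regions number of tessellation regions.
#' @param texture_alpha 1/f^alpha texture spectrum exponent.
#' @param texture_sd texture SD, cd/m2.
#' @param step_rich,step_poor boundary luminance steps (cd/m2) for
#'   bottom-up rich and poor boundaries.
#' @param step_width_deg half-width of the tapered step band, degrees.
#' @param K number of simulated annotators.
#' @param p_weak marking probability for weak (non-consensus) boundaries.
#' @param p_consensus marking probability for consensus boundaries (1).
#' @param jitter_sd annotation positional jitter SD, pixels.
#' @return object of class \code{scene_generator_config}.
#' @export
scene_generator_config <- function(height_px = 130, width_px = 200,
                                   n_regions = 8, texture_alpha = 1,
                                   texture_sd = 2, step_rich = 18,
                                   step_poor = 5, step_width_deg = 0.5,
                                   K = 5, p_weak = 0.6, p_consensus = 1,
                                   jitter_sd = 1) {
  if (n_regions < 2) sp_input_error("need at least 2 regions")
  if (!(p_weak > 0 && p_weak <= 1) || !(p_consensus > 0 && p_consensus <= 1))
    sp_input_error("marking probabilities must be in (0, 1]")
  structure(as.list(environment()), class = "scene_generator_config")
}

## 2-D 1/f^alpha noise field, zero mean, unit SD
spectral_noise <- function(nr, nc, alpha) {
  white <- matrix(stats::rnorm(nr * nc), nr, nc)
  W <- stats::fft(white)
  f <- freq_grid_cpd(nr, nc, 1)  # cycles/px
  amp <- 1 / pmax(f, 1 / max(nr, nc))^(alpha / 2)
  amp[1, 1] <- 0
  x <- Re(stats::fft(W * amp, inverse = TRUE)) / (nr * nc)
  (x - mean(x)) / stats::sd(x)
}

#' Generate a synthetic annotated scene
#'
#' Builds a Voronoi tessellation from jittered lattice seeds, adds per-
#' region 1/f texture, applies tapered luminance steps across boundaries
#' (step size set by the boundary's bottom-up type), and simulates K
#' annotators who mark each boundary with its type-specific probability and
#' positional jitter.
#'
#' @param config a [scene_generator_config].
#' @param seed integer RNG seed.
#' @return list with \code{scene} ([gray_image]), \code{annotations} (list
#'   of K binary masks), \code{truth} (per-boundary data.frame: labels i/j,
#'   td_type, bu_type, step), \code{geometry}.
#' @export
generate_scene <- function(config, seed = 1L) {
  with_seed(seed, {
    nr <- config$height_px; nc <- config$width_px
    geom <- scene_geometry(nr, nc)
    if (min(nr, nc) < 40) sp_input_error("scene too small to tessellate")

    ## jittered-lattice Voronoi seeds (keeps regions from degenerating)
    gr <- max(1, round(sqrt(config$n_regions * nr / nc)))
    gc <- max(1, ceiling(config$n_regions / gr))
    sr <- (rep(seq_len(gr), times = gc) - 0.5) / gr * nr
    sc <- (rep(seq_len(gc), each = gr) - 0.5) / gc * nc
    keep <- seq_len(config$n_regions)
    sr <- sr[keep] + stats::rnorm(length(keep), 0, nr / (4 * gr))
    sc <- sc[keep] + stats::rnorm(length(keep), 0, nc / (4 * gc))
    g <- coord_grids(nr, nc)
    d2 <- sapply(seq_along(sr), function(i)
      as.vector((g$row - sr[i])^2 + (g$col - sc[i])^2))
    lab <- matrix(max.col(-d2), nr, nc)

    ## boundary pixels keyed by unordered region pair
    right <- cbind(lab[, -1], lab[, nc])
    below <- rbind(lab[-1, ], lab[nr, ])
    bnd <- (lab != right) | (lab != below)
    other <- ifelse(lab != right, right, ifelse(lab != below, below, lab))
    pair_key <- ifelse(bnd, paste(pmin(lab, other), pmax(lab, other)), NA)
    keys <- sort(unique(pair_key[!is.na(pair_key)]))
    ## drop tiny adjacency slivers
    keys <- keys[sapply(keys, function(k) sum(pair_key == k, na.rm = TRUE)) >=
                   deg2px(1, geom)]
    if (length(keys) < 4) sp_input_error("tessellation produced too few boundaries")

    truth <- data.frame(key = keys,
                        td_type = sample(c("consensus", "weak"), length(keys),
                                         replace = TRUE),
                        bu_type = sample(c("rich", "poor"), length(keys),
                                         replace = TRUE),
                        stringsAsFactors = FALSE)
    truth$step <- ifelse(truth$bu_type == "rich", config$step_rich,
                         config$step_poor)
    truth$p_mark <- ifelse(truth$td_type == "consensus", config$p_consensus,
                           config$p_weak)

    ## tapered luminance step across each boundary
    w_px <- deg2px(config$step_width_deg, geom)
    v <- matrix(0, nr, nc)
    bmasks <- list()
    for (b in seq_len(nrow(truth))) {
      k <- truth$key[b]
      mask <- !is.na(pair_key) & pair_key == k
      bmasks[[k]] <- mask
      ij <- as.integer(strsplit(k, " ")[[1]])
      dm <- EBImage::distmap((!mask) + 0)
      band <- raised_cosine_taper(dm, w_px * 0.3, w_px * 0.7)
      side <- ifelse(lab == ij[1], 1, ifelse(lab == ij[2], -1, 0))
      v <- v + truth$step[b] / 2 * band * side
    }
    ## per-region texture: one spectral field, region-specific sign/phase by
    ## drawing an independent field per region
    tex <- matrix(0, nr, nc)
    for (i in seq_len(config$n_regions)) {
      fld <- spectral_noise(nr, nc, config$texture_alpha)
      tex[lab == i] <- fld[lab == i]
    }
    values <- geom$background_lum + v + config$texture_sd * tex
    scene <- gray_image(clip_lum(values, geom), geom, normalize = FALSE)

    ## simulated annotators
    annotations <- lapply(seq_len(config$K), function(k) {
      m <- matrix(0, nr, nc)
      for (b in seq_len(nrow(truth))) {
        if (stats::runif(1) > truth$p_mark[b]) next
        mask <- bmasks[[truth$key[b]]]
        dr <- round(stats::rnorm(1, 0, config$jitter_sd))
        dc <- round(stats::rnorm(1, 0, config$jitter_sd))
        idx <- which(mask, arr.ind = TRUE)
        idx[, 1] <- pmin(pmax(idx[, 1] + dr, 1), nr)
        idx[, 2] <- pmin(pmax(idx[, 2] + dc, 1), nc)
        m[idx] <- 1
      }
      m
    })
    list(scene = scene, annotations = annotations, truth = truth,
         geometry = geom)
  })
}

#' Build maps and select insertion points for a generated scene
#'
#' Convenience wrapper running [build_bottom_up_map()],
#' [build_top_down_map()] and [select_insertion_points()].
#'
#' @param gen output of [generate_scene()].
#' @param ... passed to [select_insertion_points()].
#' @return list with \code{maps} ([feature_maps]) and \code{points} (list of
#'   4 insertion points, or [scene_excluded]).
#' @export
scene_to_points <- function(gen, ...) {
  bu <- build_bottom_up_map(gen$scene)
  td <- build_top_down_map(gen$annotations, gen$geometry)
  maps <- feature_maps(bu, td, gen$geometry)
  list(maps = maps, points = select_insertion_points(maps, ...))
}

#' Cohort configuration for simulated experiments
#'
#' Observers are channel-domain linear-template SDT observers. Insertions
#' at top-down rich locations engage the sharp Rich-state template;
#' all others the broad Poor-state template. Each state's internal noise is
#' set so the observer lands at its target threshold-regime sensitivity
#' (the study targeted threshold performance per observer); per-subject
#' lognormal jitter adds realistic between-observer spread.
#'
#' @param n_subjects number of simulated observers.
#' @param trials_per_cell trials per (scene point category x signal class).
#' @param rho target intensity (contrast; 4 x the 0.03 noise mean).
#' @param noise_mean,noise_sd,clip_sd orientation-noise parameters.
#' @param dprime_rich,dprime_poor target sensitivities of the two states.
#' @param subject_sd lognormal SD of per-subject sensitivity jitter.
#' @param sigma_w_rich,sigma_w_poor template tuning widths (channels).
#' @param rich_axis which insertion label engages the Rich state: "td"
#'   (default), "bu", or "none" (all Poor: a null cohort).
#' @param double_pass_blocks number of 100-trial double-pass blocks per
#'   subject (second 50 trials repeat the first 50 in permuted order).
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 8, trials_per_cell = 250,
                          rho = 0.12, noise_mean = 0.03, noise_sd = 0.007,
                          clip_sd = 4, dprime_rich = 1.6, dprime_poor = 0.9,
                          subject_sd = 0.1, sigma_w_rich = 0.8,
                          sigma_w_poor = 2.5,
                          rich_axis = c("td", "bu", "none"),
                          double_pass_blocks = 0) {
  rich_axis <- match.arg(rich_axis)
  stopifnot(n_subjects >= 1, trials_per_cell >= 1)
  structure(as.list(environment()), class = "cohort_config")
}

## circular-distance Gaussian template over the 16 channels: positive bump
## at the congruent channel (5), negative at the incongruent channel (13)
state_template <- function(sigma_w) {
  k <- 1:16
  circ <- function(a, b) pmin(abs(a - b), 16 - abs(a - b))
  exp(-circ(k, 5)^2 / (2 * sigma_w^2)) - exp(-circ(k, 13)^2 / (2 * sigma_w^2))
}

## internal-noise SD delivering the target d' for a template observer
template_sigma_int <- function(template, rho, noise_sd, dprime) {
  sig_diff <- rho * (template[5] - template[13])
  sigma_tot <- sig_diff / dprime
  sigma_ext <- noise_sd * sqrt(sum(template^2))
  sqrt(max(sigma_tot^2 - sigma_ext^2, 0))
}

## clipped Gaussian noise matrix, n x 16
draw_noise <- function(n, mean, sd, clip_sd) {
  m <- matrix(stats::rnorm(n * 16, mean, sd), n, 16)
  pmin(pmax(m, mean - clip_sd * sd), mean + clip_sd * sd)
}

## batch template-observer responses for stimulus matrix S (n x 16)
template_responses <- function(S, template, sigma_int, criterion) {
  dv <- as.vector(S %*% template) +
    if (sigma_int > 0) stats::rnorm(nrow(S), 0, sigma_int) else 0
  ifelse(dv > criterion, "congruent", "incongruent")
}

#' Simulate a probe-insertion experiment
#'
#' Produces a full factorial trial table: subject x scene x insertion
#' category x signal class, using the channel-domain template-observer
#' surrogate (flagged in the \code{engine} attribute). Optional double-pass
#' blocks append 100-trial blocks whose second half repeats the first half's
#' stimuli in permuted order.
#'
#' @param points_df data.frame of insertion points (scene_id, td_label,
#'   bu_label, congruent_theta, ...), e.g. rbind-ed outputs of
#'   [insertion_points_df()]; a minimal default of one synthetic scene's
#'   four categories is used when NULL.
#' @param cohort a [cohort_config].
#' @param seed integer RNG seed.
#' @return data.frame of trial records (one row per trial) with noise
#'   columns n01..n16.
#' @export
simulate_experiment <- function(points_df = NULL, cohort = cohort_config(),
                                seed = 1L) {
  if (is.null(points_df))
    points_df <- expand.grid(scene_id = 1L,
                             td_label = c("rich", "poor"),
                             bu_label = c("rich", "poor"),
                             stringsAsFactors = FALSE)
  if (!all(c("scene_id", "td_label", "bu_label") %in% names(points_df)))
    sp_input_error("points_df needs scene_id, td_label, bu_label")
  with_seed(seed, {
    w_rich <- state_template(cohort$sigma_w_rich)
    w_poor <- state_template(cohort$sigma_w_poor)
    rows <- vector("list", 0)
    for (subj in seq_len(cohort$n_subjects)) {
      jit <- exp(stats::rnorm(1, 0, cohort$subject_sd))
      for (ip in seq_len(nrow(points_df))) {
        rich_here <- switch(cohort$rich_axis,
                            td = points_df$td_label[ip] == "rich",
                            bu = points_df$bu_label[ip] == "rich",
                            none = FALSE)
        w <- if (rich_here) w_rich else w_poor
        dtarget <- jit * if (rich_here) cohort$dprime_rich else cohort$dprime_poor
        sig <- template_sigma_int(w, cohort$rho, cohort$noise_sd, dtarget)
        crit <- sum(w) * cohort$noise_mean +
          cohort$rho * (w[5] + w[13]) / 2
        n_tr <- 2 * cohort$trials_per_cell
        q <- rep(c(1L, 0L), cohort$trials_per_cell)
        noise <- draw_noise(n_tr, cohort$noise_mean, cohort$noise_sd,
                            cohort$clip_sd)
        S <- noise
        S[q == 1, 5] <- S[q == 1, 5] + cohort$rho
        S[q == 0, 13] <- S[q == 0, 13] + cohort$rho
        resp <- template_responses(S, w, sig, crit)
        df <- data.frame(observer_id = subj,
                         scene_id = points_df$scene_id[ip],
                         insertion_id = ip,
                         td_label = points_df$td_label[ip],
                         bu_label = points_df$bu_label[ip],
                         condition = "intact", cue = "none",
                         q = q, response = resp,
                         z = as.integer((resp == "congruent") == (q == 1)),
                         block_id = NA_integer_, pass_id = "none",
                         stim_id = NA_integer_, flipped = stats::runif(n_tr) < 0.5)
        nd <- as.data.frame(noise); names(nd) <- sprintf("n%02d", 1:16)
        rows[[length(rows) + 1]] <- cbind(df, nd)
      }
      ## double-pass blocks (first insertion category's observer state)
      for (blk in seq_len(cohort$double_pass_blocks)) {
        rich_here <- cohort$rich_axis == "td" && points_df$td_label[1] == "rich"
        w <- if (rich_here) w_rich else w_poor
        dtarget <- jit * if (rich_here) cohort$dprime_rich else cohort$dprime_poor
        sig <- template_sigma_int(w, cohort$rho, cohort$noise_sd, dtarget)
        crit <- sum(w) * cohort$noise_mean + cohort$rho * (w[5] + w[13]) / 2
        q1 <- sample(rep(c(1L, 0L), 25))
        noise1 <- draw_noise(50, cohort$noise_mean, cohort$noise_sd,
                             cohort$clip_sd)
        perm <- sample(50)
        q <- c(q1, q1[perm])
        noise <- rbind(noise1, noise1[perm, ])
        stim <- c(seq_len(50), perm)
        S <- noise
        S[q == 1, 5] <- S[q == 1, 5] + cohort$rho
        S[q == 0, 13] <- S[q == 0, 13] + cohort$rho
        resp <- template_responses(S, w, sig, crit)
        df <- data.frame(observer_id = subj,
                         scene_id = points_df$scene_id[1],
                         insertion_id = 1L,
                         td_label = points_df$td_label[1],
                         bu_label = points_df$bu_label[1],
                         condition = "intact", cue = "none",
                         q = q, response = resp,
                         z = as.integer((resp == "congruent") == (q == 1)),
                         block_id = blk,
                         pass_id = rep(c("1", "2"), each = 50),
                         stim_id = stim, flipped = FALSE)
        nd <- as.data.frame(noise); names(nd) <- sprintf("n%02d", 1:16)
        rows[[length(rows) + 1]] <- cbind(df, nd)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "engine") <- "channel_surrogate"
    out
  })
}

#' Double-pass summary statistics from a trial table
#'
#' @param trials trial table containing double-pass blocks (pass_id 1/2).
#' @return list with pc, pa, p_yes and the number of pairs.
#' @export
double_pass_stats <- function(trials) {
  dp <- trials[trials$pass_id %in% c("1", "2"), ]
  if (nrow(dp) == 0) sp_input_error("no double-pass trials")
  key <- interaction(dp$observer_id, dp$block_id, dp$stim_id, drop = TRUE)
  p1 <- dp[dp$pass_id == "1", ]
  p2 <- dp[dp$pass_id == "2", ]
  k1 <- interaction(p1$observer_id, p1$block_id, p1$stim_id, drop = FALSE)
  k2 <- interaction(p2$observer_id, p2$block_id, p2$stim_id, drop = FALSE)
  m <- match(as.character(k1), as.character(k2))
  if (any(is.na(m))) sp_input_error("unmatched double-pass stimuli")
  agree <- p1$response == p2$response[m]
  list(pc = mean(c(p1$z, p2$z)), pa = mean(agree),
       p_yes = mean(c(p1$response, p2$response) == "congruent"),
       n_pairs = nrow(p1))
}

#' ERP cohort configuration
#'
#' The synthetic EEG emulates the structure targeted by the lateralized
#' analysis: a shared visual evoked response on every trial, a
#' contralateral probe-specific component over posterior electrodes scaled
#' by the probe's meridian distance, an optional top-down-rich-specific
#' occipital component in the early (0-100 ms) window, and 1/f background
#' noise. Amplitudes are in microvolts at literature-typical scales.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_condition trials per td x bu insertion category.
#' @param srate sampling rate, Hz.
#' @param n_samples epoch length in samples (1 s).
#' @param noise_rms single-trial background noise RMS, microvolts.
#' @param evoked_amp amplitudes of the P1/N1-like evoked deflections.
#' @param lateral_amp contralateral probe-component peak amplitude.
#' @param td_mod_amp,bu_mod_amp rich-specific early occipital modulation
#'   amplitudes along each map axis (bu defaults to 0: no genuine
#'   bottom-up effect).
#' @param subject_gain_sd lognormal SD of per-subject amplitude gain.
#' @return object of class \code{erp_cohort_config}.
#' @export
erp_cohort_config <- function(n_subjects = 7, trials_per_condition = 500,
                              srate = 256, n_samples = 256, noise_rms = 15,
                              evoked_amp = c(p1 = 5, n1 = -7),
                              lateral_amp = 1.5, td_mod_amp = 2,
                              bu_mod_amp = 0, subject_gain_sd = 0.1) {
  stopifnot(n_subjects >= 2, trials_per_condition >= 2)
  structure(as.list(environment()), class = "erp_cohort_config")
}

#' Generate a synthetic ERP cohort (or one subject)
#'
#' @param config an [erp_cohort_config].
#' @param seed integer RNG seed.
#' @param subject if non-NULL, generate only this subject's dataset (the
#'   result is bit-identical to that subject's slice of the full cohort).
#' @return an [erp_dataset].
#' @export
generate_erp_cohort <- function(config, seed = 1L, subject = NULL) {
  lay <- electrode_layout()
  subjects <- if (is.null(subject)) seq_len(config$n_subjects) else subject
  sets <- lapply(subjects, function(s)
    generate_erp_subject(config, lay, seed = seed + 1000L * s, subject_id = s))
  waves <- array(0, c(nrow(lay), config$n_samples,
                      sum(sapply(sets, function(x) dim(x$waveforms)[3]))))
  meta <- do.call(rbind, lapply(sets, function(x) x$meta))
  off <- 0
  for (x in sets) {
    n <- dim(x$waveforms)[3]
    waves[, , off + seq_len(n)] <- x$waveforms
    off <- off + n
  }
  erp_dataset(waves, meta, srate = config$srate, layout = lay)
}

generate_erp_subject <- function(config, lay, seed, subject_id) {
  with_seed(seed, {
    nt <- config$n_samples
    ne <- nrow(lay)
    times <- -0.2 + (seq_len(nt) - 1) / config$srate
    gauss <- function(mu, sd) exp(-(times - mu)^2 / (2 * sd^2))
    evoked_tc <- config$evoked_amp[["p1"]] * gauss(0.100, 0.030) +
                 config$evoked_amp[["n1"]] * gauss(0.170, 0.040)
    lateral_tc <- gauss(0.130, 0.035)
    mod_tc <- gauss(0.060, 0.025)

    group_gain <- c(occipital = 1, parietal = 0.8, central = 0.5,
                    frontal = 0.3)[lay$group]
    lat_gain <- c(occipital = 1, parietal = 0.6, central = 0,
                  frontal = 0)[lay$group]
    lat_gain[lay$hemisphere == "M"] <- 0
    mod_gain <- ifelse(lay$group == "occipital" & lay$hemisphere != "M", 1, 0)
    sgain <- exp(stats::rnorm(1, 0, config$subject_gain_sd))

    cells <- expand.grid(td = c("rich", "poor"), bu = c("rich", "poor"),
                         stringsAsFactors = FALSE)
    ntr <- nrow(cells) * config$trials_per_condition
    meta <- data.frame(subject_id = subject_id,
                       td_label = rep(cells$td, each = config$trials_per_condition),
                       bu_label = rep(cells$bu, each = config$trials_per_condition),
                       side = sample(c("left", "right"), ntr, replace = TRUE),
                       meridian_dist = stats::runif(ntr, 2, 8))

    ## 1/f background noise, all electrodes/trials at once
    ncol_tot <- ne * ntr
    if (config$noise_rms > 0) {
      white <- matrix(stats::rnorm(nt * ncol_tot), nt, ncol_tot)
      W <- stats::mvfft(white)
      fr <- c(0:floor(nt / 2), -(ceiling(nt / 2) - 1):-1)[1:nt] *
        config$srate / nt
      amp <- 1 / sqrt(pmax(abs(fr), 1))
      amp[1] <- 0
      noise <- Re(stats::mvfft(W * amp, inverse = TRUE)) / nt
      noise <- noise * (config$noise_rms / stats::sd(noise))
      waves <- array(aperm(array(noise, c(nt, ne, ntr)), c(2, 1, 3)),
                     c(ne, nt, ntr))
    } else {
      waves <- array(0, c(ne, nt, ntr))
    }

    contra_hemi <- ifelse(meta$side == "left", "R", "L")
    for (tr in seq_len(ntr)) {
      contra <- (lay$hemisphere == contra_hemi[tr]) + 0
      amp_lat <- config$lateral_amp * meta$meridian_dist[tr] / 5
      mod <- 0
      if (meta$td_label[tr] == "rich") mod <- mod + config$td_mod_amp
      if (meta$bu_label[tr] == "rich") mod <- mod + config$bu_mod_amp
      amp_mod <- mod * meta$meridian_dist[tr] / 5
      waves[, , tr] <- waves[, , tr] +
        sgain * (outer(group_gain, evoked_tc) +
                 outer(contra * lat_gain, amp_lat * lateral_tc) +
                 outer(contra * mod_gain, amp_mod * mod_tc))
    }
    list(waveforms = waves, meta = meta)
  })
}

#' Cohort-level rich/poor ERP modulation without holding all trials
#'
#' Generates and preprocesses each subject in turn, computes the per-
#' subject rich-minus-poor contra-minus-ipsi difference, and assembles the
#' across-subject modulation map. Output is identical to running
#' [generate_erp_cohort()] + [preprocess_erp()] + [rich_poor_modulation()]
#' on the full cohort, at a fraction of the memory.
#'
#' @param config an [erp_cohort_config].
#' @param map_axis "td", "bu", or both (each subject is generated and
#'   preprocessed once, shared across axes).
#' @param seed integer RNG seed.
#' @param regime filtering regime for [preprocess_erp()].
#' @return a \code{modulation_map}, or a named list of them when both axes
#'   are requested.
#' @export
erp_cohort_modulation <- function(config, map_axis = c("td", "bu"),
                                  seed = 1L, regime = "0.5/40") {
  map_axis <- match.arg(map_axis, several.ok = TRUE)
  per <- list(); times <- NULL
  for (s in seq_len(config$n_subjects)) {
    ds <- generate_erp_cohort(config, seed = seed, subject = s)
    ds <- preprocess_erp(ds, regime = regime)
    for (ax in map_axis) {
      lab <- ds$meta[[paste0(ax, "_label")]]
      rich <- contra_minus_ipsi(ds, sel = lab == "rich")
      poor <- contra_minus_ipsi(ds, sel = lab == "poor")
      if (is.null(per[[ax]]))
        per[[ax]] <- array(0, c(config$n_subjects, nrow(rich$diff),
                                ncol(rich$diff)),
                           dimnames = list(NULL, rich$pairs, NULL))
      per[[ax]][s, , ] <- rich$diff - poor$diff
      times <- rich$times
    }
  }
  build <- function(p, ax) {
    m <- apply(p, c(2, 3), mean)
    se <- apply(p, c(2, 3), stats::sd) / sqrt(config$n_subjects)
    z <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    ok <- se > 0
    z[ok] <- m[ok] / se[ok]
    structure(list(values = m, z = z, per_subject = p,
                   pairs = dimnames(m)[[1]], times = times,
                   subjects = seq_len(config$n_subjects), map_axis = ax),
              class = "modulation_map")
  }
  out <- Map(build, per, names(per))
  if (length(out) == 1) out[[1]] else out
}
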