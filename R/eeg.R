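## -------------------------------------------------------------------------
## Lateralized ERP analysis: epoch preprocessing, contra-minus-ipsi
## differencing, rich-minus-poor modulation maps with across-subject
## Z-scores, and window pooling.
## -------------------------------------------------------------------------

#' Default 10/20 electrode layout with homologue pairing
#'
#' 32 electrodes: 14 left/right homologue pairs plus the midline (Fz, Cz,
#' Pz, Oz), which is excluded from lateralized analysis. Each pair carries a
#' scalp-region group label used for window pooling.
#'
#' @return data.frame with columns electrode, hemisphere (L/R/M), pair,
#'   group.
#' @export
electrode_layout <- function() {
  pairs <- list(
    c("Fp1", "Fp2", "frontal"),  c("F7", "F8", "frontal"),
    c("F3", "F4", "frontal"),    c("FC5", "FC6", "central"),
    c("FC1", "FC2", "central"),  c("T7", "T8", "central"),
    c("C3", "C4", "central"),    c("CP5", "CP6", "central"),
    c("CP1", "CP2", "central"),  c("P7", "P8", "parietal"),
    c("P3", "P4", "parietal"),   c("PO7", "PO8", "occipital"),
    c("PO3", "PO4", "occipital"), c("O1", "O2", "occipital"))
  rows <- lapply(pairs, function(p) data.frame(
    electrode = c(p[1], p[2]), hemisphere = c("L", "R"),
    pair = paste0(p[1], "/", p[2]), group = p[3]))
  mid <- data.frame(electrode = c("Fz", "Cz", "Pz", "Oz"),
                    hemisphere = "M", pair = NA_character_,
                    group = c("frontal", "central", "parietal", "occipital"))
  rbind(do.call(rbind, rows), mid)
}

#' ERP dataset container
#'
#' @param waveforms numeric array electrode x time x trial, microvolts.
#' @param meta data.frame with one row per trial: subject_id, side
#'   ("left"/"right": probe hemifield), td_label, bu_label, meridian_dist
#'   (degrees from the vertical meridian).
#' @param srate sampling rate, Hz (default 256).
#' @param t_start epoch start relative to stimulus onset, seconds (-0.2).
#' @param layout electrode layout data.frame ([electrode_layout()]).
#' @return object of class \code{erp_dataset}.
#' @export
erp_dataset <- function(waveforms, meta, srate = 256, t_start = -0.2,
                        layout = electrode_layout()) {
  if (length(dim(waveforms)) != 3)
    sp_input_error("waveforms must be electrode x time x trial")
  if (dim(waveforms)[3] != nrow(meta))
    sp_input_error("metadata rows must match trial count")
  need <- c("subject_id", "side", "td_label", "bu_label", "meridian_dist")
  if (!all(need %in% names(meta)))
    sp_input_error(paste("meta must have columns:", paste(need, collapse = ", ")))
  if (dim(waveforms)[1] != nrow(layout))
    sp_input_error("waveform electrode dimension must match layout")
  times <- t_start + (seq_len(dim(waveforms)[2]) - 1) / srate
  structure(list(waveforms = waveforms, meta = meta, srate = srate,
                 times = times, layout = layout), class = "erp_dataset")
}

#' @export
print.erp_dataset <- function(x, ...) {
  d <- dim(x$waveforms)
  cat(sprintf("<erp_dataset> %d electrodes x %d samples x %d trials (%d subjects, %g Hz)\n",
              d[1], d[2], d[3], length(unique(x$meta$subject_id)), x$srate))
  invisible(x)
}

## direct-form II transposed IIR filter applied down the rows of a matrix
## (time x channels), vectorized across channels; matches signal::filter
iir_filter_mat <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  nt <- nrow(X); nc <- ncol(X)
  Y <- matrix(0, nt, nc)
  state <- matrix(0, n - 1, nc)
  for (t in seq_len(nt)) {
    x <- X[t, ]
    y <- b[1] * x + state[1, ]
    if (n > 2) {
      state[seq_len(n - 2), ] <- state[seq_len(n - 2) + 1, ] +
        outer(b[seq_len(n - 2) + 1], x) - outer(a[seq_len(n - 2) + 1], y)
    }
    state[n - 1, ] <- b[n] * x - a[n] * y
    Y[t, ] <- y
  }
  Y
}

## causal band-pass: order-2 Butterworth highpass, then an order-6
## Butterworth lowpass applied twice (forward only); the steep low-pass
## flank suppresses 50 Hz mains leakage well below the 40 Hz band edge
causal_bandpass_mat <- function(X, srate, hp, lp) {
  nyq <- srate / 2
  bh <- signal::butter(2, hp / nyq, type = "high")
  bl <- signal::butter(6, lp / nyq, type = "low")
  Y <- iir_filter_mat(bh$b, bh$a, X)
  Y <- iir_filter_mat(bl$b, bl$a, Y)
  iir_filter_mat(bl$b, bl$a, Y)
}

causal_bandpass <- function(x, srate, hp, lp) {
  as.numeric(causal_bandpass_mat(matrix(x, ncol = 1), srate, hp, lp))
}

#' Preprocess ERP epochs
#'
#' Per-epoch baseline subtraction (mean of the pre-stimulus interval),
#' causal band-pass filtering per regime ("0.5/40" or "1/20" Hz), and
#' optional linear rescaling of each trial's waveforms by the probe's
#' distance from the vertical meridian (steering averages towards trials
#' with strongly lateralized probes).
#'
#' @param dataset an [erp_dataset].
#' @param regime "0.5/40" or "1/20" (highpass/lowpass cutoffs in Hz).
#' @param rescale_meridian logical (default TRUE).
#' @return a preprocessed [erp_dataset].
#' @export
preprocess_erp <- function(dataset, regime = c("0.5/40", "1/20"),
                           rescale_meridian = TRUE) {
  regime <- match.arg(regime)
  cut <- as.numeric(strsplit(regime, "/")[[1]])
  w <- dataset$waveforms
  base_idx <- which(dataset$times < 0)
  if (length(base_idx) == 0) sp_input_error("no pre-stimulus baseline samples")
  d <- dim(w)
  ## baseline first (a constant epoch maps to exactly zero), then filter
  base <- apply(w[, base_idx, , drop = FALSE], c(1, 3), mean)
  w <- w - aperm(array(base, c(d[1], d[3], d[2])), c(1, 3, 2))
  flat <- matrix(aperm(w, c(2, 1, 3)), d[2], d[1] * d[3])
  flat <- causal_bandpass_mat(flat, dataset$srate, cut[1], cut[2])
  w <- aperm(array(flat, c(d[2], d[1], d[3])), c(2, 1, 3))
  if (rescale_meridian) {
    if (any(!is.finite(dataset$meta$meridian_dist)))
      sp_input_error("meridian_dist missing for some trials")
    scl <- dataset$meta$meridian_dist
    w <- w * rep(scl, each = d[1] * d[2])
  }
  out <- dataset
  out$waveforms <- w
  out
}

## per (electrode, probe-side) trial-average waveforms for a trial subset
side_averages <- function(dataset, sel) {
  d <- dim(dataset$waveforms)
  out <- list()
  for (s in c("left", "right")) {
    idx <- which(sel & dataset$meta$side == s)
    if (length(idx) == 0) sp_input_error(sprintf("no %s-side trials", s))
    out[[s]] <- apply(dataset$waveforms[, , idx, drop = FALSE], c(1, 2), mean)
  }
  out
}

unit_rms <- function(x) {
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

#' Contra-minus-ipsi waveforms
#'
#' For every left/right homologue pair, averages trials per probe side,
#' normalizes each electrode's average trace to unit RMS, assigns traces to
#' contralateral/ipsilateral roles per probe side, and returns the
#' contra-minus-ipsi difference per pair.
#'
#' @param dataset a (preprocessed) [erp_dataset].
#' @param electrode_group optional group name ("occipital", "central",
#'   "frontal", "parietal") restricting the pairs.
#' @param sel optional logical trial filter (default: all trials).
#' @param normalize_rms logical; normalize traces to unit RMS before
#'   differencing (default TRUE).
#' @return list with \code{diff} (pair x time matrix), \code{contra},
#'   \code{ipsi}, \code{pairs}, \code{times}.
#' @export
contra_minus_ipsi <- function(dataset, electrode_group = NULL, sel = NULL,
                              normalize_rms = TRUE) {
  lay <- dataset$layout
  if (is.null(sel)) sel <- rep(TRUE, nrow(dataset$meta))
  pair_names <- unique(lay$pair[!is.na(lay$pair)])
  if (!is.null(electrode_group)) {
    keep <- unique(lay$pair[!is.na(lay$pair) & lay$group %in% electrode_group])
    pair_names <- pair_names[pair_names %in% keep]
    if (length(pair_names) == 0) sp_config_error("no pairs in that group")
  }
  avg <- side_averages(dataset, sel)
  if (normalize_rms) {
    for (s in names(avg))
      avg[[s]] <- t(apply(avg[[s]], 1, unit_rms))
  }
  nt <- length(dataset$times)
  contra <- ipsi <- matrix(0, length(pair_names), nt,
                           dimnames = list(pair_names, NULL))
  for (i in seq_along(pair_names)) {
    el <- lay$electrode[!is.na(lay$pair) & lay$pair == pair_names[i]]
    hem <- lay$hemisphere[match(el, lay$electrode)]
    L <- which(dataset$layout$electrode == el[hem == "L"])
    R <- which(dataset$layout$electrode == el[hem == "R"])
    if (length(L) != 1 || length(R) != 1)
      sp_config_error(sprintf("unpaired electrode in %s", pair_names[i]))
    ## probe in the left hemifield -> right hemisphere is contralateral
    contra[i, ] <- (avg$left[R, ] + avg$right[L, ]) / 2
    ipsi[i, ]   <- (avg$left[L, ] + avg$right[R, ]) / 2
  }
  list(diff = contra - ipsi, contra = contra, ipsi = ipsi,
       pairs = pair_names, times = dataset$times)
}

#' Rich-minus-poor modulation map
#'
#' Per subject, computes contra-minus-ipsi waveforms separately for rich
#' and poor insertions along the chosen map axis and stores the rich-minus-
#' poor difference per electrode pair and time point; across subjects, the
#' Z score is the mean divided by the standard error.
#'
#' @param dataset a (preprocessed) [erp_dataset] containing all subjects.
#' @param map_axis "td" or "bu".
#' @param normalize_rms passed to [contra_minus_ipsi()].
#' @return object of class \code{modulation_map}: \code{values} (across-
#'   subject mean, pair x time), \code{z}, \code{per_subject} (subject x
#'   pair x time), \code{pairs}, \code{times}, \code{subjects}.
#' @export
rich_poor_modulation <- function(dataset, map_axis = c("td", "bu"),
                                 normalize_rms = TRUE) {
  map_axis <- match.arg(map_axis)
  lab <- dataset$meta[[paste0(map_axis, "_label")]]
  subjects <- sort(unique(dataset$meta$subject_id))
  if (length(subjects) < 2)
    sp_input_error("need >= 2 subjects for across-subject Z scores")
  per <- NULL
  for (i in seq_along(subjects)) {
    ssel <- dataset$meta$subject_id == subjects[i]
    rich <- contra_minus_ipsi(dataset, sel = ssel & lab == "rich",
                              normalize_rms = normalize_rms)
    poor <- contra_minus_ipsi(dataset, sel = ssel & lab == "poor",
                              normalize_rms = normalize_rms)
    if (is.null(per))
      per <- array(0, c(length(subjects), nrow(rich$diff), ncol(rich$diff)),
                   dimnames = list(NULL, rich$pairs, NULL))
    per[i, , ] <- rich$diff - poor$diff
  }
  m <- apply(per, c(2, 3), mean)
  sdv <- apply(per, c(2, 3), stats::sd)
  se <- sdv / sqrt(length(subjects))
  z <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  ok <- se > 0
  z[ok] <- m[ok] / se[ok]
  structure(list(values = m, z = z, per_subject = per,
                 pairs = dimnames(m)[[1]], times = dataset$times,
                 subjects = subjects, map_axis = map_axis),
            class = "modulation_map")
}

#' @export
print.modulation_map <- function(x, ...) {
  cat(sprintf("<modulation_map> axis=%s, %d pairs x %d samples, %d subjects; max |Z| = %.2f\n",
              x$map_axis, length(x$pairs), length(x$times),
              length(x$subjects), max(abs(x$z), na.rm = TRUE)))
  invisible(x)
}

#' Pool a modulation map within an electrode/time window
#'
#' Sums per-subject modulation values over the selected electrode pairs and
#' time window, giving one scalar per subject.
#'
#' @param map a \code{modulation_map}.
#' @param pairs electrode-pair names, or a group name from the layout
#'   ("occipital", "central", "frontal", "parietal").
#' @param t_window length-2 numeric, window in seconds relative to stimulus
#'   onset (e.g. \code{c(0, 0.1)}).
#' @return numeric vector, one pooled value per subject.
#' @export
pool_window <- function(map, pairs, t_window) {
  lay <- electrode_layout()
  if (length(pairs) == 1 && pairs %in% lay$group)
    pairs <- unique(lay$pair[!is.na(lay$pair) & lay$group == pairs])
  pi_idx <- match(pairs, map$pairs)
  if (any(is.na(pi_idx))) sp_input_error("unknown electrode pair(s)")
  ti <- which(map$times >= t_window[1] & map$times <= t_window[2])
  if (length(ti) == 0 || length(pi_idx) == 0)
    sp_input_error("empty electrode/time selection")
  apply(map$per_subject[, pi_idx, ti, drop = FALSE], 1, sum)
}
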