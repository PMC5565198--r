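## Independent oracles and fixture builders, deliberately written with naive
## direct loops so they share no code path with the package internals.

## direct 2-D correlation with replicate padding (matches EBImage filter2
## orientation for symmetric kernels; Sobel test uses both orientations)
conv2_oracle <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  kh <- (nrow(kern) - 1) / 2; kw <- (ncol(kern) - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in -kh:kh) for (b in -kw:kw) {
      ii <- min(max(i + a, 1), nr)
      jj <- min(max(j + b, 1), nc)
      acc <- acc + img[ii, jj] * kern[a + kh + 1, b + kw + 1]
    }
    out[i, j] <- acc
  }
  out
}

## bottom-up map oracle: Sobel gradient magnitude squared, RMS-pooled over a
## disc, normalized by max
bottom_up_oracle <- function(values, geometry, pool_diam_deg = 0.9) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- conv2_oracle(values, sx)
  gy <- conv2_oracle(values, t(sx))
  g2 <- gx^2 + gy^2
  d <- round(pool_diam_deg / geometry$deg_per_px)
  if (d %% 2 == 0) d <- d + 1
  d <- max(d, 3)
  h <- (d - 1) / 2
  ## footprint convention shared with the implementation; pooling itself is
  ## recomputed by direct loops below
  brush <- EBImage::makeBrush(d, shape = "disc")
  offs <- which(brush > 0, arr.ind = TRUE) - (h + 1)
  offs <- data.frame(a = offs[, 1], b = offs[, 2])
  nr <- nrow(values); nc <- ncol(values)
  pooled <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- pmin(pmax(i + offs$a, 1), nr)
    jj <- pmin(pmax(j + offs$b, 1), nc)
    pooled[i, j] <- sqrt(mean(g2[cbind(ii, jj)]))
  }
  m <- max(pooled)
  if (m <= 0) return(pooled)
  pooled / m
}

## second-moment ellipse of a binary mask via explicit eigendecomposition;
## y axis points up (negated row)
moments_oracle <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  x <- idx[, 2] - 1
  y <- -(idx[, 1] - 1)
  C <- stats::cov(cbind(x, y)) * (length(x) - 1) / length(x)
  ev <- eigen(C, symmetric = TRUE)
  l1 <- ev$values[1]; l2 <- max(ev$values[2], 0)
  vec <- ev$vectors[, 1]
  list(elongation = if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0)),
       theta = atan2(vec[2], vec[1]) %% pi)
}

## exhaustive-enumeration insertion-point oracle: independent eligibility
## computation plus lexicographic minimization over all labelled quadruples
oracle_select_points <- function(bu, td, geometry, elong_thresh = 0.9,
                                 bu_thresh = 0.1, margin_deg = 2,
                                 spacing_deg = 1.6, elong_win_deg = 1.6) {
  dpp <- geometry$deg_per_px
  nr <- nrow(td); nc <- ncol(td)
  w <- max(3, round(elong_win_deg / dpp)); if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  marg <- margin_deg / dpp
  cand <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (td[i, j] <= 0) next
    r0 <- i - 1; c0 <- j - 1
    if (r0 < marg || r0 > nr - 1 - marg || c0 < marg || c0 > nc - 1 - marg) next
    if (bu[i, j] < bu_thresh) next
    win <- td[max(1, i - h):min(nr, i + h), max(1, j - h):min(nc, j + h)]
    ## zero-pad to the full window as the map does near edges (margin makes
    ## this moot for eligible pixels)
    el <- moments_oracle(win > 0)$elongation
    if (el < elong_thresh) next
    cand <- rbind(cand, data.frame(row = r0, col = c0, bu = bu[i, j],
                                   td = td[i, j]))
  }
  if (is.null(cand)) return(NULL)
  rich <- cand[cand$td >= 1 - 1e-9, ]
  poor <- cand[cand$td < 1 - 1e-9, ]
  if (nrow(rich) < 2 || nrow(poor) < 2) return(NULL)
  min_px <- spacing_deg / dpp
  ok_pair <- function(a, b)
    (a$row - b$row)^2 + (a$col - b$col)^2 >= min_px^2
  best <- NULL; best_key <- NULL
  for (i1 in seq_len(nrow(rich))) for (i2 in seq_len(nrow(poor)))
    for (i3 in seq_len(nrow(poor))) for (i4 in seq_len(nrow(rich))) {
      p <- list(rich[i1, ], poor[i2, ], poor[i3, ], rich[i4, ])
      feasible <- TRUE
      for (a in 1:3) for (b in (a + 1):4)
        if (!ok_pair(p[[a]], p[[b]])) feasible <- FALSE
      if (!feasible) next
      key <- c(p[[1]]$bu, p[[1]]$row, p[[1]]$col,
               abs(p[[2]]$bu - p[[1]]$bu), p[[2]]$row, p[[2]]$col,
               -p[[3]]$bu, p[[3]]$row, p[[3]]$col,
               abs(p[[4]]$bu - p[[3]]$bu), p[[4]]$row, p[[4]]$col)
      if (is.null(best_key) || lex_less(key, best_key)) {
        best <- p; best_key <- key
      }
    }
  best
}

lex_less <- function(a, b, tol = 1e-12) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - tol) return(TRUE)
    if (a[k] > b[k] + tol) return(FALSE)
  }
  FALSE
}

## toy 40 x 40 map pair: thin full-width horizontal lines on the top-down
## map (elongated by construction), candidate bottom-up values planted at a
## few columns per line, sub-threshold elsewhere
toy_line_maps <- function(seed) {
  set.seed(seed)
  n <- 40
  geom <- scene_geometry(n, n)
  td <- matrix(0, n, n)
  bu <- matrix(0.05, n, n)
  rows <- c(10, 17, 24, 31)
  levels <- sample(c(1, 1, 0.6, 0.6))
  for (k in seq_along(rows)) td[rows[k], ] <- levels[k]
  n_cand <- sample(4:7, 1)
  for (m in seq_len(n_cand)) {
    r <- sample(rows, 1)
    c <- sample(10:31, 1)
    bu[r, c] <- round(stats::runif(1, 0.1, 1), 3)
  }
  list(bu = bu, td = td, geometry = geom)
}

## small low-contrast smooth scene (no luminance clipping anywhere)
make_test_scene <- function(seed = 1, nr = 96, nc = 128, amp = 6) {
  set.seed(seed)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  v <- 32 + amp * (sin(2 * pi * g$r / 23) * cos(2 * pi * g$c / 31) +
                   0.5 * sin(2 * pi * (g$r + g$c) / 17))
  gray_image(matrix(v, nr, nc), scene_geometry(nr, nc), normalize = FALSE)
}

## trial table from explicit pieces (for toy reverse-correlation cases)
toy_trials <- function(q, z, noise) {
  df <- data.frame(q = q, z = z)
  nd <- as.data.frame(noise)
  names(nd) <- sprintf("n%02d", 1:16)
  cbind(df, nd)
}

## batch template-observer trial table (shared by kernel-recovery tests)
template_trial_table <- function(n, template, rho = 0.12, noise_mean = 0.03,
                                 noise_sd = 0.007, sigma_int = 0,
                                 criterion = NULL, seed = 1) {
  set.seed(seed)
  q <- rep(c(1L, 0L), length.out = n)
  noise <- matrix(stats::rnorm(n * 16, noise_mean, noise_sd), n, 16)
  noise <- pmin(pmax(noise, noise_mean - 4 * noise_sd),
                noise_mean + 4 * noise_sd)
  S <- noise
  S[q == 1, 5] <- S[q == 1, 5] + rho
  S[q == 0, 13] <- S[q == 0, 13] + rho
  if (is.null(criterion))
    criterion <- sum(template) * noise_mean +
      rho * (template[5] + template[13]) / 2
  dv <- as.vector(S %*% template) +
    if (sigma_int > 0) stats::rnorm(n, 0, sigma_int) else 0
  resp <- ifelse(dv > criterion, "congruent", "incongruent")
  out <- toy_trials(q, as.integer((resp == "congruent") == (q == 1)), noise)
  out$response <- resp
  out
}
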