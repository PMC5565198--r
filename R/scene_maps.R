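## -------------------------------------------------------------------------
## Bottom-up (edge energy) and top-down (annotator consensus) maps, and the
## selection of the four categorized probe insertion points.
## -------------------------------------------------------------------------

## odd pixel size closest to `deg` degrees, at least `minimum`
odd_px <- function(deg, geometry, minimum = 3) {
  n <- max(minimum, round(deg2px(deg, geometry)))
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)  # d/dcol
sobel_y <- t(sobel_x)                                      # d/drow

## exact spatial correlation with replicate padding by shift-and-add
## (avoids the numerical dust of FFT-based convolution, which the map's
## max-normalization would otherwise amplify on near-constant scenes)
shift_conv <- function(v, kern) {
  nr <- nrow(v); nc <- ncol(v)
  kh <- (nrow(kern) - 1) / 2; kw <- (ncol(kern) - 1) / 2
  out <- matrix(0, nr, nc)
  for (a in -kh:kh) for (b in -kw:kw) {
    k <- kern[a + kh + 1, b + kw + 1]
    if (k == 0) next
    ri <- pmin(pmax(seq_len(nr) + a, 1), nr)
    ci <- pmin(pmax(seq_len(nc) + b, 1), nc)
    out <- out + k * v[ri, ci]
  }
  out
}

#' Bottom-up map: normalized local edge energy
#'
#' Convolves the scene with the 3x3 Sobel gradient pair, pools the squared
#' gradient magnitude by its root mean square over a disc of diameter
#' \code{pool_diam_deg} (the filter's active area), and normalizes the
#' result by its maximum so the map spans [0, 1]. A constant scene maps to
#' all zeros.
#'
#' @param scene a [gray_image].
#' @param pool_diam_deg pooling-disc diameter, degrees (default 0.9).
#' @return numeric matrix in [0, 1], same shape as the scene.
#' @export
build_bottom_up_map <- function(scene, pool_diam_deg = 0.9) {
  stopifnot(inherits(scene, "gray_image"))
  geom <- scene$geometry
  d <- odd_px(pool_diam_deg, geom)
  if (min(geom$height_px, geom$width_px) < d + 2)
    sp_config_error("scene smaller than the edge-energy filter support")
  v <- scene$values
  gx <- shift_conv(v, sobel_x)
  gy <- shift_conv(v, sobel_y)
  g2 <- gx^2 + gy^2
  disc <- EBImage::makeBrush(d, shape = "disc")
  pooled <- sqrt(pmax(shift_conv(g2, disc / sum(disc)), 0))
  m <- max(pooled)
  if (m <= 0) return(matrix(0, nrow(v), ncol(v)))
  pooled / m
}

#' Top-down map: annotator consensus proportion
#'
#' Each annotator's binary boundary drawing is thickened by morphological
#' dilation with a disc of diameter \code{line_width_deg}; the map value at a
#' pixel is the proportion of annotators whose thickened drawing covers it,
#' so values are exact multiples of 1/K.
#'
#' @param annotations list of K binary matrices ({0,1}), one per annotator.
#' @param geometry a [scene_geometry] matching the masks.
#' @param line_width_deg thickened line width, degrees (default 0.5).
#' @return numeric matrix in [0, 1].
#' @export
build_top_down_map <- function(annotations, geometry, line_width_deg = 0.5) {
  if (length(annotations) < 1) sp_input_error("need at least one annotator")
  d <- odd_px(line_width_deg, geometry)
  brush <- EBImage::makeBrush(d, shape = "disc")
  acc <- matrix(0, geometry$height_px, geometry$width_px)
  for (mask in annotations) {
    if (!all(dim(mask) == c(geometry$height_px, geometry$width_px)))
      sp_input_error("annotation mask shape does not match scene geometry")
    m <- (mask != 0) + 0
    acc <- acc + EBImage::dilate(m, brush)
  }
  acc / length(annotations)
}

#' Paired feature maps
#'
#' @param bottom_up,top_down co-registered maps in [0, 1].
#' @param geometry a [scene_geometry].
#' @return Object of class \code{feature_maps}.
#' @export
feature_maps <- function(bottom_up, top_down, geometry) {
  if (!all(dim(bottom_up) == dim(top_down)))
    sp_input_error("bottom-up and top-down maps must share shape")
  stopifnot(all(dim(bottom_up) == c(geometry$height_px, geometry$width_px)))
  structure(list(bottom_up = bottom_up, top_down = top_down,
                 geometry = geometry), class = "feature_maps")
}

#' @export
print.feature_maps <- function(x, ...) {
  cat(sprintf("<feature_maps> %d x %d px; BU max %.3f; TD consensus pixels %d\n",
              nrow(x$bottom_up), ncol(x$bottom_up), max(x$bottom_up),
              sum(x$top_down >= 1 - 1e-9)))
  invisible(x)
}

## second-moment summary of weighted pixel coordinates; y axis points up
## (negated row) so orientations are counterclockwise from the +x (col) axis
region_moments <- function(weights) {
  n <- sum(weights)
  if (n <= 0) sp_undefined_value("empty region: moments undefined")
  idx <- which(weights > 0, arr.ind = TRUE)
  w <- weights[weights > 0]
  x <- idx[, 2] - 1
  y <- -(idx[, 1] - 1)
  mx <- sum(w * x) / n; my <- sum(w * y) / n
  list(mxx = sum(w * (x - mx)^2) / n,
       myy = sum(w * (y - my)^2) / n,
       mxy = sum(w * (x - mx) * (y - my)) / n)
}

moments_to_elongation <- function(mxx, myy, mxy) {
  tr <- (mxx + myy) / 2
  dd <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr + dd
  l2 <- pmax(tr - dd, 0)
  ifelse(l1 <= 0, 0, sqrt(pmax(1 - l2 / l1, 0)))
}

#' Elongation of a binary region
#'
#' Eccentricity of the ellipse sharing the region's second moments:
#' \code{sqrt(1 - b^2/a^2)} for semi-axes a >= b (half-focal separation over
#' semi-major axis). Ranges from 0 (circle-like) to 1 (line-like).
#'
#' @param mask binary matrix (nonzero = region).
#' @return numeric in [0, 1].
#' @export
elongation <- function(mask) {
  m <- region_moments((mask != 0) + 0)
  moments_to_elongation(m$mxx, m$myy, m$mxy)
}

## windowed elongation of the nonzero top-down pixels, evaluated at every
## pixel via box-filter moment sums (square window of side `win_deg`)
elongation_map <- function(td, geometry, win_deg = 1.6) {
  w <- odd_px(win_deg, geometry)
  box <- matrix(1, w, w)
  I <- (td > 0) + 0
  nr <- nrow(td); nc <- ncol(td)
  g <- coord_grids(nr, nc)
  x <- g$col; y <- -g$row
  f <- function(z) EBImage::filter2(z, box, boundary = 0)
  n   <- f(I)
  sx  <- f(I * x);  sy  <- f(I * y)
  sxx <- f(I * x^2); syy <- f(I * y^2); sxy <- f(I * x * y)
  ok <- n > 0
  mxx <- myy <- mxy <- matrix(0, nr, nc)
  mxx[ok] <- sxx[ok] / n[ok] - (sx[ok] / n[ok])^2
  myy[ok] <- syy[ok] / n[ok] - (sy[ok] / n[ok])^2
  mxy[ok] <- sxy[ok] / n[ok] - (sx[ok] / n[ok]) * (sy[ok] / n[ok])
  el <- matrix(0, nr, nc)
  el[ok] <- moments_to_elongation(mxx[ok], myy[ok], mxy[ok])
  el
}

#' Congruent orientation at a point
#'
#' Orientation of the major axis of the best-fitting (second-moment) ellipse
#' to the nonzero top-down pixels within a square window centred on the
#' point; counterclockwise from the image x-axis, wrapped to [0, pi).
#'
#' @param maps a [feature_maps].
#' @param point length-2 integer (row, col), 0-based.
#' @param win_deg window side, degrees (default 0.8).
#' @return orientation in radians, [0, pi).
#' @export
congruent_orientation <- function(maps, point, win_deg = 0.8) {
  geom <- maps$geometry
  w <- odd_px(win_deg, geom)
  h <- (w - 1) / 2
  r0 <- max(0, point[1] - h); r1 <- min(geom$height_px - 1, point[1] + h)
  c0 <- max(0, point[2] - h); c1 <- min(geom$width_px - 1, point[2] + h)
  win <- maps$top_down[(r0:r1) + 1, (c0:c1) + 1, drop = FALSE]
  if (all(win == 0))
    sp_undefined_value("no nonzero top-down pixels in orientation window")
  m <- region_moments((win > 0) + 0)
  theta <- 0.5 * atan2(2 * m$mxy, m$mxx - m$myy)
  theta %% pi
}

#' Insertion point record
#' @keywords internal
insertion_point <- function(row, col, td_label, bu_label, congruent_theta,
                            matched_value) {
  structure(list(row = row, col = col, td_label = td_label,
                 bu_label = bu_label, congruent_theta = congruent_theta,
                 matched_value = matched_value), class = "insertion_point")
}

#' @export
print.insertion_point <- function(x, ...) {
  cat(sprintf("<insertion_point> (%d,%d) td=%s bu=%s theta=%.3f match=%.3f\n",
              x$row, x$col, x$td_label, x$bu_label, x$congruent_theta,
              x$matched_value))
  invisible(x)
}

#' Select the four categorized probe insertion points
#'
#' Eligible pixels are nonzero on the top-down map, have windowed elongation
#' >= 0.9 and bottom-up value >= 0.1, and lie at least \code{margin_deg} from
#' the image edge. Top-down "rich" pixels have full consensus (value 1);
#' "poor" pixels have partial consensus. Slots are filled in the order
#' rich/poor, poor/poor, poor/rich, rich/rich (top-down/bottom-up labels):
#' the rich/poor slot takes the TD-rich pixel with the smallest bottom-up
#' value v; poor/poor the TD-poor pixel with bottom-up value closest to v;
#' poor/rich the TD-poor pixel with the largest bottom-up value V; rich/rich
#' the TD-rich pixel with bottom-up value closest to V. The four points must
#' be pairwise at least \code{spacing_deg} apart; the search is greedy in the
#' stated order with backtracking (next-best candidate under the slot's
#' criterion when spacing fails; ties broken row-major), so the result is
#' deterministic.
#'
#' @param maps a [feature_maps].
#' @param elong_thresh,bu_thresh eligibility thresholds (0.9, 0.1).
#' @param margin_deg edge margin in degrees (2).
#' @param spacing_deg minimum pairwise distance in degrees (1.6).
#' @param elong_win_deg window for the elongation computation (1.6).
#' @return list of 4 \code{insertion_point}s named
#'   \code{rich_poor, poor_poor, poor_rich, rich_rich}, or a
#'   [scene_excluded] signal.
#' @export
select_insertion_points <- function(maps, elong_thresh = 0.9,
                                    bu_thresh = 0.1, margin_deg = 2,
                                    spacing_deg = 1.6,
                                    elong_win_deg = 1.6) {
  geom <- maps$geometry
  td <- maps$top_down; bu <- maps$bottom_up
  el <- elongation_map(td, geom, elong_win_deg)
  nr <- nrow(td); nc <- ncol(td)
  marg <- deg2px(margin_deg, geom)
  g <- coord_grids(nr, nc)
  in_margin <- g$row >= marg & g$row <= (nr - 1 - marg) &
               g$col >= marg & g$col <= (nc - 1 - marg)
  eligible <- td > 0 & el >= elong_thresh & bu >= bu_thresh & in_margin
  if (!any(eligible)) return(scene_excluded("no eligible pixels"))
  idx <- which(eligible, arr.ind = TRUE)
  cand <- data.frame(row = idx[, 1] - 1, col = idx[, 2] - 1,
                     bu = bu[eligible], td = td[eligible])
  rich <- cand[cand$td >= 1 - 1e-9, ]
  poor <- cand[cand$td < 1 - 1e-9, ]
  if (nrow(rich) < 2 || nrow(poor) < 2)
    return(scene_excluded("fewer than two TD-rich or TD-poor candidates"))

  min_px <- deg2px(spacing_deg, geom)
  far_enough <- function(p, chosen) {
    for (q in chosen)
      if ((p$row - q$row)^2 + (p$col - q$col)^2 < min_px^2) return(FALSE)
    TRUE
  }
  order_by <- function(df, key) df[order(key, df$row, df$col), , drop = FALSE]

  ## depth-first search over the four slots; candidate order at each slot is
  ## the slot's optimality criterion, so the first complete assignment is the
  ## greedy-with-backtracking solution. A deterministic work budget bounds
  ## pathological backtracking on near-infeasible scenes; exhausting it
  ## excludes the scene.
  budget <- new.env()
  budget$left <- 200000L
  search <- function(slot, chosen) {
    if (slot == 5) return(chosen)
    cands <- switch(slot,
      order_by(rich, rich$bu),                              # rich/poor: min BU
      order_by(poor, abs(poor$bu - chosen[[1]]$bu)),        # poor/poor: near v
      order_by(poor, -poor$bu),                             # poor/rich: max BU
      order_by(rich, abs(rich$bu - chosen[[3]]$bu)))        # rich/rich: near V
    for (i in seq_len(nrow(cands))) {
      budget$left <- budget$left - 1L
      if (budget$left < 0L) return("budget")
      p <- cands[i, ]
      if (!far_enough(p, chosen)) next
      res <- search(slot + 1, c(chosen, list(p)))
      if (is.character(res)) return(res)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  sel <- search(1, list())
  if (is.character(sel))
    return(scene_excluded("candidate search budget exhausted"))
  if (is.null(sel))
    return(scene_excluded("no spacing-compatible labelled quadruple"))

  v <- sel[[1]]$bu; V <- sel[[3]]$bu
  labels <- list(c("rich", "poor"), c("poor", "poor"),
                 c("poor", "rich"), c("rich", "rich"))
  matched <- c(v, v, V, V)
  out <- vector("list", 4)
  names(out) <- c("rich_poor", "poor_poor", "poor_rich", "rich_rich")
  for (k in 1:4) {
    p <- sel[[k]]
    theta <- congruent_orientation(maps, c(p$row, p$col))
    out[[k]] <- insertion_point(p$row, p$col, labels[[k]][1], labels[[k]][2],
                                theta, matched[k])
  }
  out
}

#' Insertion points as a data frame
#'
#' @param points list of insertion points (as returned by
#'   [select_insertion_points()]).
#' @param scene_id identifier recycled across rows.
#' @return data.frame with columns scene_id, row, col, td_label, bu_label,
#'   congruent_theta, matched_value.
#' @export
insertion_points_df <- function(points, scene_id = NA) {
  do.call(rbind, lapply(points, function(p)
    data.frame(scene_id = scene_id, row = p$row, col = p$col,
               td_label = p$td_label, bu_label = p$bu_label,
               congruent_theta = p$congruent_theta,
               matched_value = p$matched_value)))
}
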