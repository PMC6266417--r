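#' Isolate the subject and detect body edges
#'
#' Converts an RGB frontal-plane image to grayscale, binarizes it into a
#' figure mask (figure assumed darker than background unless
#' `invert_contrast`), detects edges with the Canny method, and splits the
#' edge map into upper- and lower-body regions at the waist row (the row of
#' minimum figure width between shoulders and hips, unless `split_row` is
#' given).
#'
#' @param img `silhouette_image`, H x W x 3 array, or grayscale matrix.
#' @param invert_contrast Set `TRUE` for a light figure on dark background.
#' @param sigma,low,high Passed to [canny_edges()].
#' @param split_row Optional row index overriding the automatic waist split.
#' @return Object of class `subject_edges`: list with logical `upper` and
#'   `lower` edge maps (full-size, zero outside their region), the full
#'   `edges` map, figure `mask`, `gray` matrix, binarization `threshold`,
#'   `split_row`, and mask-derived `frame` landmarks (feet row, estimated
#'   body height in px, centre column, waist row/midpoint, bounding box).
#' @export
isolate_subject <- function(img, invert_contrast = FALSE, sigma = 1,
                            low = NULL, high = NULL, split_row = NULL) {
  if (inherits(img, "silhouette_image")) img <- img$img
  gray <- rgb_to_gray(img)
  if (invert_contrast) gray <- 1 - gray
  rng <- range(gray)
  thr <- mean(rng)
  mask <- gray < thr
  edges <- canny_edges(gray, sigma = sigma, low = low, high = high)
  if (diff(rng) < 0.05 || !any(mask) || !any(edges)) {
    stop("no subject detected: image has no figure/background contrast")
  }
  frame <- mask_frame(mask)
  if (is.null(split_row)) split_row <- frame$waist_row
  upper <- edges; upper[seq_len(nrow(edges)) > split_row, ] <- FALSE
  lower <- edges; lower[seq_len(nrow(edges)) <= split_row, ] <- FALSE
  structure(
    list(upper = upper, lower = lower, edges = edges, mask = mask,
         gray = gray, threshold = thr, split_row = split_row, frame = frame),
    class = "subject_edges"
  )
}

# runs of TRUE in a logical vector: matrix with columns start, end
runs_of <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# coarse landmarks from the figure mask, in image coordinates
mask_frame <- function(mask) {
  rows_any <- which(rowSums(mask) > 0)
  cols_any <- which(colSums(mask) > 0)
  top <- rows_any[1]; feet <- rows_any[length(rows_any)]
  h <- feet - top
  if (h < 20) stop("no subject detected: figure too small")
  ref_row <- round(top + 0.42 * h)
  x_c <- mean(which(mask[ref_row, ]))
  # waist: minimum width of the central run over the torso-only band
  band <- round(top + 0.30 * h):round(top + 0.48 * h)
  widths <- vapply(band, function(r) {
    rn <- runs_of(mask[r, ])
    if (nrow(rn) == 0) return(NA_real_)
    k <- which(rn[, 1] <= x_c & rn[, 2] >= x_c)
    if (length(k) == 0) k <- which.min(pmin(abs(rn[, 1] - x_c), abs(rn[, 2] - x_c)))
    rn[k[1], 2] - rn[k[1], 1] + 1
  }, numeric(1))
  waist_row <- band[which.min(widths)]
  rn <- runs_of(mask[waist_row, ])
  k <- which(rn[, 1] <= x_c & rn[, 2] >= x_c)[1]
  waist_mid_x <- mean(c(rn[k, 1], rn[k, 2]))
  list(top = top, feet = feet, height_px = h, x_center = x_c,
       waist_row = waist_row, waist_mid_x = waist_mid_x,
       col_min = cols_any[1], col_max = cols_any[length(cols_any)])
}

# subpixel boundary positions of the dark run containing index `at` along a
# grayscale profile; linear interpolation of the threshold crossing
refine_run <- function(gvec, thr, at) {
  m <- gvec < thr
  rn <- runs_of(m)
  k <- which(rn[, 1] <= at & rn[, 2] >= at)
  if (length(k) == 0) return(NULL)
  j0 <- rn[k[1], 1]; j1 <- rn[k[1], 2]
  pl <- if (j0 > 1 && gvec[j0 - 1] > gvec[j0]) {
    (j0 - 1) + (gvec[j0 - 1] - thr) / (gvec[j0 - 1] - gvec[j0])
  } else j0 - 0.5
  pr <- if (j1 < length(gvec) && gvec[j1 + 1] > gvec[j1]) {
    j1 + (thr - gvec[j1]) / (gvec[j1 + 1] - gvec[j1])
  } else j1 + 0.5
  c(pl, pr)
}

# cluster sorted integer indices with gaps <= gap into groups; returns list
cluster_indices <- function(idx, gap = 2L) {
  if (length(idx) == 0) return(list())
  br <- c(0L, which(diff(idx) > gap), length(idx))
  lapply(seq_len(length(br) - 1L), function(i) idx[(br[i] + 1L):br[i + 1L]])
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

#' Fit a limb axis by midpoint regression
#'
#' Scans the edge map along rows (for near-vertical limbs) or columns (for
#' near-horizontal limbs) inside a pixel window. On each scan line, edge
#' pixels are clustered into crossings; lines with exactly two crossings
#' contribute the midpoint of the outer edge pair, localized to subpixel
#' precision from the grayscale profile. Scan lines whose edge-pair
#' separation deviates from the median by more than `thickness_tol`
#' (relative) are treated as not being clean cross-sections of the limb
#' (joint regions, overlaps) and are dropped. A least-squares line through
#' the surviving midpoints gives the segment axis.
#'
#' @param iso A `subject_edges` object from [isolate_subject()].
#' @param window List with integer `rows = c(r0, r1)` and `cols = c(c0, c1)`.
#' @param scan `"rows"` scans horizontal lines (midpoints in x, for
#'   near-vertical segments); `"cols"` scans vertical lines (midpoints in y,
#'   for near-horizontal segments).
#' @param label Segment label carried on the result.
#' @param exclude Optional list of exclusion zones, each
#'   `list(a = c(x, y), b = c(x, y), r = radius_px)`; edge crossings within
#'   distance `r` of segment a--b are ignored (used to mask the adjoining
#'   limb near a joint).
#' @param thickness_tol Relative tolerance around the median edge-pair
#'   separation.
#' @param min_lines Minimum number of usable midpoints.
#' @return Object of class `segment_line`: list with `point` (x, y),
#'   `direction` (unit vector, image coordinates), `label`, `n_midpoints`,
#'   `n_skipped`, and the midpoint coordinates.
#' @export
fit_segment_axis <- function(iso, window, scan = c("rows", "cols"),
                             label = "segment", exclude = list(),
                             thickness_tol = 0.06, min_lines = 2L) {
  scan <- match.arg(scan)
  stopifnot(inherits(iso, "subject_edges"))
  edges <- iso$edges; gray <- iso$gray; thr <- iso$threshold
  H <- nrow(edges); W <- ncol(edges)
  r0 <- max(1L, window$rows[1]); r1 <- min(H, window$rows[2])
  c0 <- max(1L, window$cols[1]); c1 <- min(W, window$cols[2])
  if (r1 <= r0 || c1 <= c0) stop("segment not resolvable: empty window [", label, "]")

  lines_at <- if (scan == "rows") r0:r1 else c0:c1
  perp <- if (scan == "rows") c0:c1 else r0:r1
  mids <- numeric(0); pos <- numeric(0); sep <- numeric(0)
  n_skipped <- 0L
  for (s in lines_at) {
    evec <- if (scan == "rows") edges[s, perp] else edges[perp, s]
    cl <- cluster_indices(which(evec))
    if (length(cl) > 0 && length(exclude) > 0) {
      keep <- vapply(cl, function(ix) {
        cen <- perp[round(mean(ix))]
        p <- if (scan == "rows") c(cen, s) else c(s, cen)
        !any(vapply(exclude, function(z) {
          dist_point_segment(p, z$a, z$b) <= z$r
        }, logical(1)))
      }, logical(1))
      cl <- cl[keep]
    }
    if (length(cl) != 2) { n_skipped <- n_skipped + 1L; next }
    centers <- perp[round(vapply(cl, mean, numeric(1)))]
    at <- round(mean(centers)) - perp[1] + 1L
    gvec <- if (scan == "rows") gray[s, perp] else gray[perp, s]
    bnd <- refine_run(gvec, thr, at)
    if (is.null(bnd)) { n_skipped <- n_skipped + 1L; next }
    m <- mean(bnd) + perp[1] - 1
    mids <- c(mids, m); pos <- c(pos, s); sep <- c(sep, diff(bnd))
  }
  if (length(mids) >= min_lines) {
    med <- stats::median(sep)
    ok <- abs(sep - med) <= thickness_tol * med
    mids <- mids[ok]; pos <- pos[ok]
  }
  if (length(mids) < min_lines) {
    stop("segment not resolvable: fewer than ", min_lines,
         " usable midpoints [", label, "]")
  }
  # regress midpoint on scan position
  b <- stats::cov(mids, pos) / stats::var(pos)
  a <- mean(mids) - b * mean(pos)
  if (scan == "rows") {
    # x = a + b*y -> direction (b, 1) in image coords
    point <- c(a + b * mean(pos), mean(pos)); dirv <- c(b, 1)
    mx <- mids; my <- pos
  } else {
    point <- c(mean(pos), a + b * mean(pos)); dirv <- c(1, b)
    mx <- pos; my <- mids
  }
  dirv <- dirv / sqrt(sum(dirv^2))
  structure(
    list(point = point, direction = dirv, label = label,
         n_midpoints = length(mids), n_skipped = n_skipped,
         midpoints = cbind(x = mx, y = my)),
    class = "segment_line"
  )
}

#' @export
print.segment_line <- function(x, ...) {
  ang <- atan2(-x$direction[2], x$direction[1]) * 180 / pi
  cat(sprintf("<segment_line %s: %.2f deg (math), n=%d, skipped=%d>\n",
              x$label, ang, x$n_midpoints, x$n_skipped))
  invisible(x)
}

#' Longitudinal body axis from waist and thigh-gap midpoints
#'
#' The axis is the line through two points: the midpoint of the upper body
#' at waist height, and the midpoint between the two thighs close to the
#' knees. Both are localized to subpixel precision from the grayscale
#' profile of their row.
#'
#' @param iso A `subject_edges` object.
#' @param proportions Body-proportion prior, see [body_proportions()].
#' @return A `segment_line` (direction pointing up the body) with the two
#'   defining midpoints retained in `$midpoints`.
#' @export
body_axis <- function(iso, proportions = body_proportions()) {
  stopifnot(inherits(iso, "subject_edges"))
  fr <- iso$frame; thr <- iso$threshold
  # waist midpoint (refined)
  gvec <- iso$gray[fr$waist_row, ]
  bnd <- refine_run(gvec, thr, round(fr$waist_mid_x))
  if (is.null(bnd)) stop("body axis unresolvable at the waist row")
  waist <- c(mean(bnd), fr$waist_row)
  # thigh-gap midpoint close to the knees
  knee_row <- round(fr$feet - proportions$thigh_gap_probe_y * fr$height_px)
  gvec <- iso$gray[knee_row, ]
  m <- gvec < thr
  rn <- runs_of(m)
  if (nrow(rn) < 2) stop("body axis unresolvable at the thigh row: expected two legs")
  cen <- (rn[, 1] + rn[, 2]) / 2
  ord <- order(abs(cen - fr$x_center))[1:2]
  ord <- ord[order(cen[ord])]
  left_leg <- refine_run(gvec, thr, round(cen[ord[1]]))
  right_leg <- refine_run(gvec, thr, round(cen[ord[2]]))
  gap_mid <- mean(c(left_leg[2], right_leg[1]))
  thigh <- c(gap_mid, knee_row)
  dirv <- waist - thigh
  dirv <- dirv / sqrt(sum(dirv^2))
  structure(
    list(point = waist, direction = dirv, label = "body_axis",
         n_midpoints = 2L, n_skipped = 0L,
         midpoints = rbind(waist = waist, thigh_gap = thigh)),
    class = "segment_line"
  )
}

# unit direction in math convention (y up) from an image-coordinate line
math_dir <- function(line) c(line$direction[1], -line$direction[2])

angle_between <- function(u, v) {
  d <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(max(d, -1), 1)) * 180 / pi
}

#' Arm and trunk angles from fitted segment lines
#'
#' Computes the elbow angle alpha (forearm vs upper arm), shoulder angle
#' beta (upper arm vs longitudinal body axis) and trunk tilt gamma (body
#' axis vs the gravitational axis, i.e. the image vertical). Left and right
#' sides are computed separately. Fitted lines are undirected; they are
#' oriented anatomically before differencing: the body axis points up, upper
#' arms point laterally away from the body axis, forearms point up. Alpha is
#' the interior angle at the elbow (between the forearm direction and the
#' elbow-to-shoulder direction), so the full range (0, 180) is preserved.
#'
#' @param lines Named list of `segment_line` objects with elements
#'   `forearm_left`, `forearm_right`, `upperarm_left`, `upperarm_right`,
#'   `body_axis`.
#' @return Object of class `arm_angles`: `alpha_left`, `alpha_right`,
#'   `beta_left`, `beta_right` in degrees in \[0, 180\], and unsigned
#'   `gamma` in \[0, 90\].
#' @export
compute_angles <- function(lines) {
  need <- c("forearm_left", "forearm_right", "upperarm_left",
            "upperarm_right", "body_axis")
  missing <- setdiff(need, names(lines))
  if (length(missing) > 0) {
    stop("missing segment line(s): ", paste(missing, collapse = ", "))
  }
  up <- math_dir(lines$body_axis)
  if (up[2] < 0) up <- -up
  gamma <- angle_between(up, c(0, 1))

  orient <- function(v, positive_x = NULL, positive_y = NULL) {
    if (!is.null(positive_x) && sign(v[1]) != (if (positive_x) 1 else -1)) v <- -v
    if (!is.null(positive_y) && v[2] < 0) v <- -v
    v
  }
  ua_r <- orient(math_dir(lines$upperarm_right), positive_x = TRUE)
  ua_l <- orient(math_dir(lines$upperarm_left), positive_x = FALSE)
  fa_r <- orient(math_dir(lines$forearm_right), positive_y = TRUE)
  fa_l <- orient(math_dir(lines$forearm_left), positive_y = TRUE)

  structure(
    list(
      alpha_left = angle_between(fa_l, -ua_l),
      alpha_right = angle_between(fa_r, -ua_r),
      beta_left = angle_between(ua_l, up),
      beta_right = angle_between(ua_r, up),
      gamma = gamma
    ),
    class = "arm_angles"
  )
}

#' @export
print.arm_angles <- function(x, ...) {
  cat(sprintf(
    "<arm_angles alpha=(%.2f, %.2f), beta=(%.2f, %.2f), gamma=%.2f deg>\n",
    x$alpha_left, x$alpha_right, x$beta_left, x$beta_right, x$gamma))
  invisible(x)
}

#' Deviation from the joint-position-sense target pose
#'
#' The target is alpha = 90, beta = 90, gamma = 0. Absolute deviations are
#' averaged over body sides for alpha and beta; gamma is a single unsigned
#' trunk angle. Per-side deviations are retained.
#'
#' @param angles An `arm_angles` object.
#' @return Object of class `jps_deviation` with `dev_alpha`, `dev_beta`,
#'   `dev_gamma` (degrees, all >= 0) and a `per_side` list.
#' @export
jps_deviation <- function(angles) {
  stopifnot(inherits(angles, "arm_angles"))
  per_side <- list(
    alpha_left = abs(angles$alpha_left - 90),
    alpha_right = abs(angles$alpha_right - 90),
    beta_left = abs(angles$beta_left - 90),
    beta_right = abs(angles$beta_right - 90)
  )
  structure(
    list(
      dev_alpha = (per_side$alpha_left + per_side$alpha_right) / 2,
      dev_beta = (per_side$beta_left + per_side$beta_right) / 2,
      dev_gamma = abs(angles$gamma),
      per_side = per_side
    ),
    class = "jps_deviation"
  )
}

# point on `line` whose horizontal offset from the body axis equals dx_px
# (sign picks the body side); linear solve in the line parameter
point_at_lateral_offset <- function(line, axis, dx_px) {
  # axis x at height y: x_a(y) = axis$point[1] + (y - axis$point[2]) * ax
  ax <- axis$direction[1] / axis$direction[2]
  p <- line$point; d <- line$direction
  # solve p1 + t d1 - (a1 + (p2 + t d2 - a2) * ax) = dx_px
  num <- dx_px - p[1] + axis$point[1] + (p[2] - axis$point[2]) * ax
  den <- d[1] - d[2] * ax
  t <- num / den
  p + t * d
}

#' Extract joint-position-sense angles from a silhouette image
#'
#' Full marker-less measurement chain: subject isolation and Canny edge
#' detection, limb search windows from the body-proportion prior, midpoint
#' regression for both upper arms (vertical scan lines, since the pose holds
#' the upper arms near horizontal) and both forearms (horizontal scan lines,
#' forearms near vertical), body axis from the waist and thigh-gap
#' midpoints, angle computation and deviation scoring. Forearm windows are
#' anchored at the elbow, estimated as the point on the fitted upper-arm
#' axis at the expected lateral distance from the body axis; edge crossings
#' near the upper-arm axis are excluded from the forearm scan so that arm
#' poses overlapping in image rows do not contaminate each other.
#'
#' @param img `silhouette_image`, RGB array, or grayscale matrix.
#' @param proportions Body-proportion prior, see [body_proportions()].
#' @param invert_contrast,sigma Passed to [isolate_subject()].
#' @return List with `angles` (`arm_angles`), `deviation`
#'   (`jps_deviation`), `lines` (the five fitted `segment_line`s), and the
#'   `subject_edges` object as `iso`.
#' @export
extract_jps <- function(img, proportions = body_proportions(),
                        invert_contrast = FALSE, sigma = 1) {
  iso <- isolate_subject(img, invert_contrast = invert_contrast, sigma = sigma)
  fr <- iso$frame
  h <- fr$height_px
  axis <- body_axis(iso, proportions)

  ua_line <- function(side) {
    sgn <- if (side == "right") 1 else -1
    cols <- sort(round(fr$x_center + sgn * c(0.17, 0.245) * h))
    # rows where, inside these columns, only the upper arm can appear: an
    # inward-crossing forearm stays above 0.885 h and the torso flank stays
    # below 0.68 h for any pose in the working range
    rows <- round(c(fr$feet - 0.885 * h, fr$feet - 0.68 * h))
    fit_segment_axis(iso, list(rows = rows, cols = cols), scan = "cols",
                     label = paste0("upperarm_", side))
  }
  ua_r <- ua_line("right"); ua_l <- ua_line("left")

  elbow_dist <- proportions$shoulder_joint_x +
    proportions$upperarm_length * cos(20 * pi / 180)
  fa_line <- function(side, ua) {
    sgn <- if (side == "right") 1 else -1
    elbow <- point_at_lateral_offset(ua, axis, sgn * elbow_dist * h)
    inner <- point_at_lateral_offset(ua, axis, sgn * 0.08 * h)
    rows <- round(c(fr$top - 2, elbow[2] - 0.04 * h))
    cols <- if (side == "right") {
      round(c(fr$x_center + 0.115 * h, fr$col_max + 2))
    } else {
      round(c(fr$col_min - 2, fr$x_center - 0.115 * h))
    }
    fit_segment_axis(
      iso, list(rows = rows, cols = cols), scan = "rows",
      label = paste0("forearm_", side),
      exclude = list(list(a = inner, b = elbow, r = 0.05 * h))
    )
  }
  fa_r <- fa_line("right", ua_r); fa_l <- fa_line("left", ua_l)

  lines <- list(forearm_left = fa_l, forearm_right = fa_r,
                upperarm_left = ua_l, upperarm_right = ua_r,
                body_axis = axis)
  angles <- compute_angles(lines)
  list(angles = angles, deviation = jps_deviation(angles),
       lines = lines, iso = iso)
}

# draw a straight segment into an RGB array by dense parameter stepping
draw_segment <- function(img, a, b, col = c(0, 0, 0), dashed = FALSE) {
  n <- max(2L, ceiling(2 * sqrt(sum((b - a)^2))))
  t <- seq(0, 1, length.out = n)
  if (dashed) t <- t[(seq_along(t) %/% 6) %% 2 == 0]
  x <- round(a[1] + t * (b[1] - a[1]))
  y <- round(a[2] + t * (b[2] - a[2]))
  ok <- x >= 1 & x <= dim(img)[2] & y >= 1 & y <= dim(img)[1]
  for (ch in 1:3) img[cbind(y[ok], x[ok], ch)] <- col[ch]
  img
}

draw_star <- function(img, p, col = c(1, 1, 1), r = 4) {
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    img <- draw_segment(img, p - r * d, p + r * d, col = col)
  }
  img
}

#' Annotated overlay image of a joint-position-sense measurement
#'
#' Draws the measurement geometry back onto the input image: the
#' longitudinal body axis (white line), the gravitational axis through the
#' waist midpoint (white dashed vertical), the fitted upper-arm and forearm
#' orientation lines (black), and stars on the two axis-defining midpoints.
#'
#' @param img The analyzed image (`silhouette_image` or RGB array).
#' @param result Result of [extract_jps()] on that image.
#' @param path Optional PNG output path.
#' @return The annotated H x W x 3 array (invisibly if `path` is given).
#' @export
annotate_jps <- function(img, result, path = NULL) {
  if (inherits(img, "silhouette_image")) img <- img$img
  stopifnot(length(dim(img)) == 3)
  ln <- result$lines
  ext <- function(line, len) {
    cbind(line$point - len * line$direction, line$point + len * line$direction)
  }
  h <- result$iso$frame$height_px
  ax <- ext(ln$body_axis, 0.45 * h)
  img <- draw_segment(img, ax[, 1], ax[, 2], col = c(1, 1, 1))
  wm <- ln$body_axis$midpoints[1, ]
  img <- draw_segment(img, c(wm[1], wm[2] - 0.45 * h),
                      c(wm[1], wm[2] + 0.35 * h), col = c(1, 1, 1),
                      dashed = TRUE)
  for (nm in c("upperarm_left", "upperarm_right", "forearm_left",
               "forearm_right")) {
    sg <- ext(ln[[nm]], 0.11 * h)
    img <- draw_segment(img, sg[, 1], sg[, 2], col = c(0, 0, 0))
  }
  for (k in 1:2) img <- draw_star(img, ln$body_axis$midpoints[k, ])
  if (!is.null(path)) {
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}
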