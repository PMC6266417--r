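#' Pose parameters for the silhouette renderer
#'
#' Describes the arm-and-trunk configuration of a rendered frontal-plane
#' figure. `alpha` is the elbow angle between forearm and upper arm, `beta`
#' the angle between upper arm and the longitudinal body axis, and `gamma`
#' the signed tilt of the body axis away from the gravitational (vertical)
#' axis, positive tilting the head towards image right. The target pose of
#' the joint-position-sense test is `alpha = beta = 90`, `gamma = 0`.
#'
#' @param alpha_left,alpha_right Elbow angles in degrees, in (0, 180).
#' @param beta_left,beta_right Shoulder angles in degrees, in (0, 180).
#' @param gamma Signed trunk tilt in degrees, |gamma| < 30.
#' @param scale_px Pixels per body height.
#' @param image_w,image_h Image dimensions in pixels.
#' @return An object of class `pose_params`.
#' @export
pose_params <- function(alpha_left = 90, alpha_right = 90,
                        beta_left = 90, beta_right = 90,
                        gamma = 0,
                        scale_px = 350, image_w = 400, image_h = 440) {
  stopifnot(
    alpha_left > 0, alpha_left < 180, alpha_right > 0, alpha_right < 180,
    beta_left > 0, beta_left < 180, beta_right > 0, beta_right < 180,
    abs(gamma) < 30,
    scale_px > 0, image_w > 0, image_h > 0
  )
  structure(
    list(alpha_left = alpha_left, alpha_right = alpha_right,
         beta_left = beta_left, beta_right = beta_right, gamma = gamma,
         scale_px = scale_px, image_w = image_w, image_h = image_h),
    class = "pose_params"
  )
}

# Shapes + landmarks in image coordinates (origin top-left, x right, y down).
silhouette_geometry <- function(pose) {
  bp <- body_proportions()
  g <- pose$gamma
  piv <- c(0, bp$pivot_y)

  # arm directions in the y-up body frame; angles in math convention
  dir <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))
  th_ua_r <- 90 - pose$beta_right
  th_ua_l <- 90 + pose$beta_left
  th_fa_r <- th_ua_r + (180 - pose$alpha_right)
  th_fa_l <- th_ua_l - (180 - pose$alpha_left)

  sh_r <- c(bp$shoulder_joint_x, bp$shoulder_joint_y)
  sh_l <- c(-bp$shoulder_joint_x, bp$shoulder_joint_y)
  el_r <- sh_r + bp$upperarm_length * dir(th_ua_r)
  el_l <- sh_l + bp$upperarm_length * dir(th_ua_l)
  wr_r <- el_r + bp$forearm_length * dir(th_fa_r)
  wr_l <- el_l + bp$forearm_length * dir(th_fa_l)

  shapes <- list(
    list(type = "disc", c = c(0, bp$head_center_y), r = bp$head_radius),
    list(type = "bar", a = c(0, bp$shoulder_y - 0.02), b = c(0, bp$head_center_y),
         w = 2 * bp$neck_halfwidth),
    list(type = "quad", v = list(  # torso, shoulder to waist
      c(-bp$shoulder_halfwidth, bp$shoulder_y), c(bp$shoulder_halfwidth, bp$shoulder_y),
      c(bp$waist_halfwidth, bp$waist_y), c(-bp$waist_halfwidth, bp$waist_y))),
    list(type = "quad", v = list(  # torso, waist to hip
      c(-bp$waist_halfwidth, bp$waist_y), c(bp$waist_halfwidth, bp$waist_y),
      c(bp$hip_halfwidth, bp$hip_y), c(-bp$hip_halfwidth, bp$hip_y))),
    list(type = "bar", a = sh_r, b = el_r, w = bp$upperarm_width),
    list(type = "bar", a = sh_l, b = el_l, w = bp$upperarm_width),
    list(type = "bar", a = el_r, b = wr_r, w = bp$forearm_width),
    list(type = "bar", a = el_l, b = wr_l, w = bp$forearm_width),
    list(type = "bar", a = c(bp$leg_center_x, bp$hip_y), b = c(bp$leg_center_x, 0),
         w = 2 * bp$leg_halfwidth),
    list(type = "bar", a = c(-bp$leg_center_x, bp$hip_y), b = c(-bp$leg_center_x, 0),
         w = 2 * bp$leg_halfwidth)
  )

  landmarks_body <- list(
    shoulder_right = sh_r, shoulder_left = sh_l,
    elbow_right = el_r, elbow_left = el_l,
    wrist_right = wr_r, wrist_left = wr_l,
    waist_mid = c(0, bp$waist_y),
    thigh_gap_mid = c(0, bp$thigh_gap_probe_y),
    feet_mid = c(0, 0), head_top = c(0, 1)
  )

  # tilt the whole figure, then map body frame (y up) -> image frame (y down)
  cx <- (pose$image_w + 1) / 2  # midpoint of the pixel-centre grid
  y0 <- pose$image_h - 0.07 * pose$scale_px  # feet margin
  to_img <- function(p) {
    p <- rotate_cw(p, g, piv)
    c(cx + pose$scale_px * p[1], y0 - pose$scale_px * p[2])
  }
  shapes <- lapply(shapes, function(sh) {
    out <- sh
    if (sh$type == "bar") {
      out$a <- to_img(sh$a); out$b <- to_img(sh$b); out$w <- sh$w * pose$scale_px
    } else if (sh$type == "quad") {
      out$v <- lapply(sh$v, to_img)
    } else {
      out$c <- to_img(sh$c); out$r <- sh$r * pose$scale_px
    }
    out
  })
  landmarks <- lapply(landmarks_body, to_img)
  list(shapes = shapes, landmarks = landmarks)
}

#' Render a silhouette image with known ground truth
#'
#' Draws a filled humanoid figure (head, neck, waisted torso, two legs, and
#' arms whose upper-arm and forearm segments follow the pose angles) as a
#' uniform dark figure on a light background. Limb widths are constant along
#' each segment, so the midpoint line between a limb's outer edges is
#' exactly its axis and the pose is recoverable analytically.
#'
#' @param pose A [pose_params()] object.
#' @param supersample Integer subpixel sampling factor per axis; values > 1
#'   antialias the boundary, which improves edge localization downstream.
#' @param fg,bg Foreground (figure) and background gray levels in \[0, 1\].
#' @return An object of class `silhouette_image`: list with `img` (H x W x 3
#'   array in \[0, 1\]), `pose` (ground truth) and `landmarks` (image
#'   coordinates of joints and axis-defining points).
#' @export
generate_silhouette <- function(pose, supersample = 2L, fg = 0.15, bg = 0.95) {
  stopifnot(inherits(pose, "pose_params"), supersample >= 1)
  geom <- silhouette_geometry(pose)
  W <- as.integer(pose$image_w); H <- as.integer(pose$image_h)

  # frame check on shape extreme points
  ext <- do.call(rbind, lapply(geom$shapes, shape_points))
  margin <- 2
  if (any(ext[, 1] < margin | ext[, 1] > W - margin |
          ext[, 2] < margin | ext[, 2] > H - margin)) {
    stop("pose geometry places the figure outside the image frame; ",
         "reduce scale_px or enlarge the image")
  }

  ss <- as.integer(supersample)
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  cov <- matrix(0, nrow = H, ncol = W)
  px0 <- rep(seq_len(W), each = H)
  py0 <- rep(seq_len(H), times = W)
  for (ox in off) for (oy in off) {
    inside <- rep(FALSE, H * W)
    px <- px0 + ox; py <- py0 + oy
    for (sh in geom$shapes) inside <- inside | shape_inside(sh, px, py)
    cov <- cov + matrix(inside, nrow = H, ncol = W)
  }
  cov <- cov / ss^2
  gray <- bg + (fg - bg) * cov
  img <- array(gray, dim = c(H, W, 3))
  structure(list(img = img, pose = pose, landmarks = geom$landmarks),
            class = "silhouette_image")
}

#' @export
print.silhouette_image <- function(x, ...) {
  p <- x$pose
  cat(sprintf(
    "<silhouette_image %dx%d px, alpha=(%.1f, %.1f), beta=(%.1f, %.1f), gamma=%.1f>\n",
    p$image_w, p$image_h, p$alpha_left, p$alpha_right,
    p$beta_left, p$beta_right, p$gamma))
  invisible(x)
}

#' Write / read a silhouette image as 8-bit RGB PNG
#'
#' @param x A `silhouette_image` or a plain H x W x 3 array in \[0, 1\].
#' @param path Output file path.
#' @return `write_silhouette_png()` returns `path` invisibly;
#'   `read_silhouette_png()` returns an H x W x 3 array in \[0, 1\].
#' @export
write_silhouette_png <- function(x, path) {
  img <- if (inherits(x, "silhouette_image")) x$img else x
  png::writePNG(img, target = path)
  invisible(path)
}

#' @rdname write_silhouette_png
#' @export
read_silhouette_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  img
}
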