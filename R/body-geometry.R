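#' Body-proportion prior used by the silhouette renderer
#'
#' All lengths are fractions of total body height (feet to top of head).
#' The same constants serve two purposes: the synthetic renderer draws the
#' figure from them, and the joint-position-sense extractor uses them as a
#' prior to place its limb search windows. Limb widths are constant along
#' each segment, so the midpoint line of a limb's outer edges is exactly the
#' segment axis and rendered ground truth is analytically exact.
#'
#' @return Named list of proportion constants.
#' @export
body_proportions <- function() {
  list(
    head_radius    = 0.065,
    head_center_y  = 0.935,
    neck_halfwidth = 0.030,
    shoulder_y     = 0.82,   # torso top
    waist_y        = 0.62,
    hip_y          = 0.50,
    shoulder_halfwidth = 0.12,
    waist_halfwidth    = 0.08,
    hip_halfwidth      = 0.11,
    shoulder_joint_x   = 0.115,
    shoulder_joint_y   = 0.80,
    upperarm_length = 0.185,
    upperarm_width  = 0.050,
    forearm_length  = 0.165,
    forearm_width   = 0.042,
    leg_center_x    = 0.065,
    leg_halfwidth   = 0.0425,
    thigh_gap_probe_y = 0.28, # "close to the knees"
    pivot_y         = 0.50    # tilt pivot (hip height)
  )
}

# ---- internal shape primitives (image-coordinate rasterization) ----

# clockwise rotation by `deg` about `pivot` in a y-up frame
rotate_cw <- function(p, deg, pivot = c(0, 0)) {
  g <- deg * pi / 180
  x <- p[1] - pivot[1]; y <- p[2] - pivot[2]
  c(x * cos(g) + y * sin(g), -x * sin(g) + y * cos(g)) + pivot
}

# A shape is a list: type "bar" (segment a->b with width w), "quad"
# (4 vertices, convex, CCW or CW), or "disc" (center, radius).
shape_points <- function(sh) {
  switch(sh$type,
    bar = {
      u <- sh$b - sh$a
      L <- sqrt(sum(u^2))
      u <- u / L
      v <- c(-u[2], u[1]) * (sh$w / 2)
      rbind(sh$a + v, sh$a - v, sh$b + v, sh$b - v)
    },
    quad = do.call(rbind, sh$v),
    disc = rbind(sh$c + c(sh$r, 0), sh$c - c(sh$r, 0),
                 sh$c + c(0, sh$r), sh$c - c(0, sh$r))
  )
}

# inside test for vectors of point coordinates px, py
shape_inside <- function(sh, px, py) {
  switch(sh$type,
    bar = {
      u <- sh$b - sh$a
      L <- sqrt(sum(u^2))
      u <- u / L
      dx <- px - sh$a[1]; dy <- py - sh$a[2]
      t <- dx * u[1] + dy * u[2]
      d <- -dx * u[2] + dy * u[1]
      t >= 0 & t <= L & abs(d) <= sh$w / 2
    },
    quad = {
      v <- sh$v
      sgn <- sign_of_quad(v)
      inside <- rep(TRUE, length(px))
      for (k in seq_len(4)) {
        a <- v[[k]]; b <- v[[if (k == 4) 1 else k + 1]]
        cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
        inside <- inside & (cr * sgn >= 0)
      }
      inside
    },
    disc = (px - sh$c[1])^2 + (py - sh$c[2])^2 <= sh$r^2
  )
}

sign_of_quad <- function(v) {
  s <- 0
  for (k in seq_len(4)) {
    a <- v[[k]]; b <- v[[if (k == 4) 1 else k + 1]]
    s <- s + (b[1] - a[1]) * (b[2] + a[2])
  }
  if (s > 0) -1 else 1
}
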