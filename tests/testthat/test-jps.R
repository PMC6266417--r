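# shared renders for this file (rendering is the expensive step)
target_img <- generate_silhouette(pose_params())
tilted_img <- generate_silhouette(pose_params(gamma = 3))

test_that("blank or contrastless images raise 'no subject detected'", {
  blank <- array(0.95, dim = c(120, 100, 3))
  expect_error(isolate_subject(blank), "no subject detected")
})

test_that("edge map matches image dimensions and hugs the figure boundary", {
  iso <- isolate_subject(target_img)
  expect_equal(dim(iso$edges), dim(iso$gray))
  expect_equal(dim(iso$upper), dim(iso$edges))
  # edge pixels trace the figure boundary: almost all within 1 px of the
  # mask boundary, every one within 2.5 px (smoothing rounds sharp corners)
  m <- iso$mask
  H <- nrow(m); W <- ncol(m)
  interior <- m & shift_down(m) & shift_up(m) & shift_left(m) & shift_right(m)
  bnd <- which(m & !interior, arr.ind = TRUE)
  ed <- which(iso$edges, arr.ind = TRUE)
  d <- vapply(seq_len(nrow(ed)), function(k) {
    sqrt(min((bnd[, 1] - ed[k, 1])^2 + (bnd[, 2] - ed[k, 2])^2))
  }, numeric(1))
  expect_gte(mean(d <= 1), 0.99)
  expect_lte(max(d), 2.5)
  # upper/lower split partitions the edges at the waist row
  expect_identical(iso$edges, iso$upper | iso$lower)
  expect_false(any(iso$upper & iso$lower))
})

test_that("a constant-width vertical bar is fitted exactly on its axis", {
  gray <- matrix(0.95, 160, 90)
  gray[20:140, 41:52] <- 0.15  # bar centred at x = 46.5
  # build an isolation object directly from a synthetic grayscale matrix
  img <- array(rep(gray, 3), dim = c(dim(gray), 3))
  iso <- isolate_subject(img)
  line <- fit_segment_axis(iso, list(rows = c(40, 120), cols = c(20, 80)),
                           scan = "rows", label = "bar")
  expect_gt(line$n_midpoints, 50)
  expect_equal(line$point[1], 46.5, tolerance = 1e-6)
  expect_equal(abs(line$direction[2]), 1, tolerance = 1e-6)
})

test_that("scan lines with an occluded edge are skipped, fit still returned", {
  gray <- matrix(0.95, 160, 90)
  gray[20:140, 41:52] <- 0.15
  img <- array(rep(gray, 3), dim = c(dim(gray), 3))
  iso <- isolate_subject(img)
  full <- fit_segment_axis(iso, list(rows = c(40, 120), cols = c(20, 80)),
                           scan = "rows")
  iso$edges[60:62, ] <- FALSE  # occlude three scan lines entirely
  part <- fit_segment_axis(iso, list(rows = c(40, 120), cols = c(20, 80)),
                           scan = "rows")
  expect_equal(part$n_midpoints, full$n_midpoints - 3)
  expect_gt(part$n_skipped, 0)
  expect_equal(part$point[1], 46.5, tolerance = 1e-6)
})

test_that("unresolvable segments raise 'segment not resolvable'", {
  iso <- isolate_subject(target_img)
  expect_error(
    fit_segment_axis(iso, list(rows = c(1, 12), cols = c(1, 12))),
    "segment not resolvable")
})

test_that("body axis of the untilted figure is vertical through its midpoints", {
  iso <- isolate_subject(target_img)
  ax <- body_axis(iso)
  ang <- compute_angles(extract_jps(target_img)$lines)
  expect_equal(ang$gamma, 0, tolerance = 0.2)
  # the axis passes within 1 px of both defining midpoints
  for (k in 1:2) {
    p <- ax$midpoints[k, ]
    v <- p - ax$point
    d <- abs(v[1] * ax$direction[2] - v[2] * ax$direction[1])
    expect_lt(d, 1)
  }
})

test_that("a 3-degree trunk tilt is recovered within 0.5 degrees", {
  res <- extract_jps(tilted_img)
  expect_equal(res$angles$gamma, 3, tolerance = 0.5)
})

test_that("the target pose scores (90, 90, 0) and zero deviation", {
  res <- extract_jps(target_img)
  a <- res$angles
  expect_equal(a$alpha_left, 90, tolerance = 0.5)
  expect_equal(a$alpha_right, 90, tolerance = 0.5)
  expect_equal(a$beta_left, 90, tolerance = 0.5)
  expect_equal(a$beta_right, 90, tolerance = 0.5)
  expect_equal(a$gamma, 0, tolerance = 0.5)
  dv <- res$deviation
  expect_lt(dv$dev_alpha + dv$dev_beta + dv$dev_gamma, 1)
})

test_that("swapping left/right labels of a symmetric pose leaves angles unchanged", {
  lines <- extract_jps(target_img)$lines
  swapped <- lines
  swapped$forearm_left <- lines$forearm_right
  swapped$forearm_right <- lines$forearm_left
  swapped$upperarm_left <- lines$upperarm_right
  swapped$upperarm_right <- lines$upperarm_left
  a <- compute_angles(lines); b <- compute_angles(swapped)
  expect_equal(a$alpha_left, b$alpha_right, tolerance = 1e-9)
  expect_equal(a$beta_left, b$beta_right, tolerance = 1e-9)
  expect_equal(a$gamma, b$gamma, tolerance = 1e-9)
})

test_that("compute_angles names any missing line", {
  lines <- extract_jps(target_img)$lines
  expect_error(compute_angles(lines[-1]), "forearm_left")
})

test_that("deviation scoring follows its stated arithmetic", {
  a <- structure(list(alpha_left = 95, alpha_right = 87, beta_left = 90,
                      beta_right = 90, gamma = 0), class = "arm_angles")
  d <- jps_deviation(a)
  expect_equal(d$dev_alpha, 4)
  expect_equal(d$dev_beta, 0)
  expect_equal(d$dev_gamma, 0)
  expect_true(all(unlist(d[c("dev_alpha", "dev_beta", "dev_gamma")]) >= 0))
})

test_that("deviations are invariant to image resolution", {
  p1 <- pose_params(alpha_left = 82, alpha_right = 97, beta_left = 101,
                    beta_right = 86, gamma = -2)
  p2 <- pose_params(alpha_left = 82, alpha_right = 97, beta_left = 101,
                    beta_right = 86, gamma = -2,
                    scale_px = 250, image_w = 300, image_h = 320)
  d1 <- extract_jps(generate_silhouette(p1))$deviation
  d2 <- extract_jps(generate_silhouette(p2))$deviation
  expect_equal(d1$dev_alpha, d2$dev_alpha, tolerance = 0.4)
  expect_equal(d1$dev_beta, d2$dev_beta, tolerance = 0.4)
  expect_equal(d1$dev_gamma, d2$dev_gamma, tolerance = 0.4)
})

test_that("extraction is deterministic bit for bit", {
  r1 <- extract_jps(tilted_img)$angles
  r2 <- extract_jps(tilted_img)$angles
  expect_identical(r1, r2)
})

test_that("rotating the image shifts gamma by the rotation and leaves alpha", {
  library(EBImage)
  p <- pose_params(alpha_left = 85, alpha_right = 95, beta_left = 95,
                   beta_right = 85, gamma = 0)
  s <- generate_silhouette(p)
  base <- extract_jps(s)$angles
  # EBImage works on x-y transposed arrays
  eb <- Image(aperm(s$img, c(2, 1, 3)), colormode = "Color")
  rot <- rotate(eb, angle = -2, bg.col = "white",
                output.dim = dim(eb)[1:2])
  arr <- aperm(as.array(rot), c(2, 1, 3))
  res <- extract_jps(arr)$angles
  expect_equal(res$gamma, base$gamma + 2, tolerance = 1)
  expect_equal(res$alpha_left, base$alpha_left, tolerance = 1)
  expect_equal(res$alpha_right, base$alpha_right, tolerance = 1)
})
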