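# Brute-force oracle for the four balance metrics: evaluates the analytic
# damped sinusoid on an `os`-times oversampled grid and recomputes each
# metric by direct scan/sum, independent of the package implementation.
oracle_balance_metrics <- function(A, lam, f, fs = 50, os = 10,
                                   pert = 2, post = 20, win = 7) {
  t <- seq(0, pert + post, by = 1 / (fs * os))
  tau <- pmax(t - pert, 0)
  x <- A * exp(-lam * tau) * sin(2 * pi * f * tau)
  x[t < pert] <- 0
  iw <- t >= pert + post - win - 1e-9 & t <= pert + post + 1e-9
  base <- mean(x[iw])
  thr <- max(abs(x[iw] - base))
  ip <- which(t >= pert - 1e-9 & t <= pert + post + 1e-9)
  e <- abs(x[ip] - base)
  pk <- which.max(e)
  ov <- which(e > thr + 1e-12); ov <- ov[ov >= pk]
  ir <- if (length(ov) == 0) pk else ov[length(ov)] + 1
  idx <- ip[1]:ip[ir]
  dev <- abs(x[idx] - base)
  c(threshold = thr,
    time = t[ip[ir]] - pert,
    distance = sum(abs(diff(x[idx]))),
    area = sum(diff(t[idx]) * (dev[-1] + dev[-length(dev)]) / 2))
}

# random pose in the sweep range used throughout the angle-recovery checks
random_sweep_pose <- function(...) {
  pose_params(alpha_left = runif(1, 70, 110), alpha_right = runif(1, 70, 110),
              beta_left = runif(1, 70, 110), beta_right = runif(1, 70, 110),
              gamma = runif(1, -5, 5), ...)
}

# absolute recovery errors of the five angles for one rendered pose
pose_recovery_errors <- function(pose) {
  res <- extract_jps(generate_silhouette(pose))
  a <- res$angles
  c(abs(a$alpha_left - pose$alpha_left),
    abs(a$alpha_right - pose$alpha_right),
    abs(a$beta_left - pose$beta_left),
    abs(a$beta_right - pose$beta_right),
    abs(a$gamma - abs(pose$gamma)))
}

# seeded normal draws that leave the session RNG alone
with_seed_rnorm <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rnorm(n, 0, sd)
}

# 4-neighbour shifts with FALSE padding, for boundary extraction
shift_down <- function(m) rbind(m[-1, , drop = FALSE], FALSE)
shift_up <- function(m) rbind(FALSE, m[-nrow(m), , drop = FALSE])
shift_left <- function(m) cbind(m[, -1, drop = FALSE], FALSE)
shift_right <- function(m) cbind(FALSE, m[, -ncol(m), drop = FALSE])

# quick null study table: one outcome, random intercept + noise, no effect
null_study <- function(seed, n_subjects = 9, sessions = c(13, 13),
                       subject_sd = 2, noise_cv = 0.01,
                       cycle = cycle_none()) {
  generate_cycle_dataset(
    study_design(n_subjects = n_subjects, sessions = sessions, seed = seed),
    list(effect_spec("Y", 50, subject_sd = subject_sd, noise_cv = noise_cv,
                     cycle = cycle)))
}
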