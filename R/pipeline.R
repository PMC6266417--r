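#' Configuration for the end-to-end synthetic study pipeline
#'
#' Bundles every knob of the simulate - extract - model chain: the study
#' design, the body-composition effect specifications, the pose variability
#' of the joint-position-sense test (per-subject bias SD and per-session SD
#' for each angle, clamped to the renderer-safe range), the
#' perturbation-trial parameter variability, and the analysis settings.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_subjects,sessions,cycle_length_days Study design, see
#'   [study_design()].
#' @param effects Outcome specifications, see [default_study_effects()].
#' @param ecw_slope Convenience: linear cycle effect planted on ECW (l/day)
#'   when `effects` is left at its default.
#' @param jps Pose variability: list with `subject_sd` and `session_sd`
#'   (named vectors over alpha, beta, gamma, degrees) and renderer size
#'   settings.
#' @param balance Trial parameter variability: lognormal subject/trial
#'   multipliers around mean amplitude, damping and frequency, plus sway
#'   noise SD.
#' @param settle_mode,alpha Analysis settings, see [compute_time()] and
#'   [test_coefficients()].
#' @param lmm_outcomes Outcomes to model; `NULL` means all body-composition
#'   outcomes plus the extracted JPS deviations and balance metrics.
#' @param cor_group_a,cor_group_b Variable groups for the correlation
#'   screen.
#' @param out_dir Optional directory for CSV/JSON artifacts; `NULL` keeps
#'   everything in memory.
#' @param write_images Also write per-session silhouette PNGs and trace
#'   CSVs under `out_dir` (slower, for audit).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(
    seed = 1L, n_subjects = 9, sessions = c(12, 14), cycle_length_days = 28,
    effects = NULL, ecw_slope = 0,
    jps = list(subject_sd = c(alpha = 3, beta = 6, gamma = 1),
               session_sd = c(alpha = 2.5, beta = 3, gamma = 0.8),
               scale_px = 300, image_w = 360, image_h = 380),
    balance = list(amplitude = 10, damping = 0.5, freq = 1.8,
                   subject_cv = 0.2, trial_cv = 0.15, noise_sd = 0.05,
                   y_gain = 0.6),
    settle_mode = "settling", alpha = 0.05,
    lmm_outcomes = NULL,
    cor_group_a = c("time", "threshold", "distance_x", "distance_y",
                    "area_x", "area_y"),
    cor_group_b = c("dev_alpha", "dev_beta", "dev_gamma", "TBW", "ECW", "ICW"),
    out_dir = NULL, write_images = FALSE) {
  if (is.null(effects)) effects <- default_study_effects(ecw_slope)
  cfg <- list(seed = as.integer(seed), n_subjects = n_subjects,
              sessions = sessions, cycle_length_days = cycle_length_days,
              effects = effects, jps = jps, balance = balance,
              settle_mode = settle_mode, alpha = alpha,
              lmm_outcomes = lmm_outcomes,
              cor_group_a = cor_group_a, cor_group_b = cor_group_b,
              out_dir = out_dir, write_images = write_images)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML document may set any scalar field of [pipeline_config()]
#' (`seed`, `n_subjects`, `sessions`, `cycle_length_days`, `ecw_slope`,
#' `settle_mode`, `alpha`, `out_dir`, `write_images`, correlation groups).
#'
#' @param path YAML file path.
#' @return Object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- intersect(names(y), names(formals(pipeline_config)))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, y[known])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# per-session JPS measurement: sample a pose around the target, render it,
# run the extractor; returns the three deviations
simulate_jps_session <- function(subj_bias, session_sd, jps_cfg) {
  pose <- pose_params(
    alpha_left = clamp(90 + subj_bias["alpha"] + stats::rnorm(1, 0, session_sd["alpha"]), 72, 108),
    alpha_right = clamp(90 + subj_bias["alpha"] + stats::rnorm(1, 0, session_sd["alpha"]), 72, 108),
    beta_left = clamp(90 + subj_bias["beta"] + stats::rnorm(1, 0, session_sd["beta"]), 72, 108),
    beta_right = clamp(90 + subj_bias["beta"] + stats::rnorm(1, 0, session_sd["beta"]), 72, 108),
    gamma = clamp(subj_bias["gamma"] + stats::rnorm(1, 0, session_sd["gamma"]), -4.8, 4.8),
    scale_px = jps_cfg$scale_px, image_w = jps_cfg$image_w,
    image_h = jps_cfg$image_h)
  img <- generate_silhouette(pose)
  res <- extract_jps(img)
  list(image = img, deviation = res$deviation)
}

#' Run the full synthetic study pipeline
#'
#' Simulates the longitudinal study table, renders and scores one
#' joint-position-sense image per session, simulates and scores four
#' perturbation trials per session (left/right leg x medial/lateral,
#' aggregated to one value per metric), merges everything with the
#' allocated cycle day, fits the biquadratic random-coefficient model to
#' every outcome with the combined test of time-dependent terms, runs the
#' correlation screen between balance and proprioception/body-water
#' variables, and computes two-day binned means. Identical configuration
#' and seed reproduce the report bit for bit.
#'
#' @param config A [pipeline_config()], or a YAML path accepted by
#'   [read_pipeline_config()].
#' @return Object of class `pipeline_report`: list with `sessions` (merged
#'   per-session table), `lmm` (per-outcome list with `fit` and `test`),
#'   `verdicts` (tibble outcome/F/p/verdict), `correlations`, `binned`
#'   (named list of two-day bin tables), and `log` (stage log tibble).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  t_start <- Sys.time()
  note <- function(stage, detail) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, detail = detail,
      elapsed_s = round(as.numeric(difftime(Sys.time(), t_start, units = "secs")), 2))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  # stage seeds, all derived from the master seed
  seeds <- with_local_seed(config$seed, sample.int(2^30, 4))

  study <- stage("simulate_study", {
    design <- study_design(n_subjects = config$n_subjects,
                           sessions = config$sessions,
                           cycle_length_days = config$cycle_length_days,
                           seed = seeds[1])
    generate_cycle_dataset(design, config$effects)
  })
  note("simulate_study", sprintf("%d rows, %d subjects", nrow(study),
                                 length(unique(study$subject_id))))

  jps_tab <- stage("jps", with_local_seed(seeds[2], {
    sdv <- config$jps$subject_sd
    subjects <- unique(study$subject_id)
    bias <- lapply(subjects, function(s) {
      stats::setNames(stats::rnorm(3, 0, sdv[c("alpha", "beta", "gamma")]),
                      c("alpha", "beta", "gamma"))
    })
    names(bias) <- subjects
    rows <- lapply(seq_len(nrow(study)), function(k) {
      res <- simulate_jps_session(bias[[study$subject_id[k]]],
                                  config$jps$session_sd, config$jps)
      if (config$write_images && !is.null(out_dir)) {
        dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
        write_silhouette_png(res$image, file.path(
          out_dir, "images",
          sprintf("%s_s%02d.png", study$subject_id[k], study$session[k])))
      }
      dv <- res$deviation
      tibble::tibble(dev_alpha = dv$dev_alpha, dev_beta = dv$dev_beta,
                     dev_gamma = dv$dev_gamma)
    })
    do.call(rbind, rows)
  }))
  note("jps", sprintf("%d images scored", nrow(jps_tab)))

  bal_tab <- stage("balance", with_local_seed(seeds[3], {
    b <- config$balance
    subjects <- unique(study$subject_id)
    smul <- lapply(subjects, function(s) stats::rlnorm(3, 0, b$subject_cv))
    names(smul) <- subjects
    combos <- expand.grid(leg = c("left", "right"),
                          direction = c("medial", "lateral"),
                          stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(study)), function(k) {
      sm <- smul[[study$subject_id[k]]]
      trials <- lapply(seq_len(nrow(combos)), function(j) {
        tm <- stats::rlnorm(3, 0, b$trial_cv)
        pars <- balance_sim_params(
          pert_time_s = stats::runif(1, 0.5, 5),
          amplitude = b$amplitude * sm[1] * tm[1],
          damping = b$damping * sm[2] * tm[2],
          freq = b$freq * sm[3] * tm[3],
          noise_sd = b$noise_sd, y_gain = b$y_gain,
          seed = sample.int(2^30, 1))
        tr <- generate_balance_trace(pars, leg = combos$leg[j],
                                     direction = combos$direction[j])
        if (config$write_images && !is.null(out_dir)) {
          dir.create(file.path(out_dir, "traces"), showWarnings = FALSE)
          write_balance_trace(tr, file.path(
            out_dir, "traces",
            sprintf("%s_s%02d_%s_%s.csv", study$subject_id[k],
                    study$session[k], combos$leg[j], combos$direction[j])))
        }
        balance_metrics(tr, settle_mode = config$settle_mode)
      })
      aggregate_trials(do.call(rbind, trials))$subject
    })
    do.call(rbind, rows)
  }))
  note("balance", sprintf("%d sessions x 4 trials scored", nrow(bal_tab)))

  sessions <- stage("merge", {
    stopifnot(nrow(jps_tab) == nrow(study), nrow(bal_tab) == nrow(study))
    tibble::as_tibble(cbind(as.data.frame(study), jps_tab, bal_tab))
  })
  note("merge", sprintf("%d rows, %d columns", nrow(sessions), ncol(sessions)))

  outcomes <- config$lmm_outcomes
  if (is.null(outcomes)) {
    outcomes <- c(names(config$effects), "dev_alpha", "dev_beta", "dev_gamma",
                  "threshold", "time", "distance_x", "distance_y",
                  "area_x", "area_y")
  }
  lmm <- stage("lmm", {
    res <- lapply(outcomes, function(oc) {
      fit_cycle_lmm(sessions, oc, alpha = config$alpha)
    })
    names(res) <- outcomes
    res
  })
  verdicts <- tibble::tibble(
    outcome = outcomes,
    F = vapply(lmm, function(r) r$test$F, 0),
    df1 = vapply(lmm, function(r) r$test$df1, 0),
    df2 = vapply(lmm, function(r) r$test$df2, 0),
    p_value = vapply(lmm, function(r) r$test$p_value, 0),
    verdict = vapply(lmm, function(r) r$test$verdict, "")
  )
  note("lmm", sprintf("%d outcomes, %d constant-model", nrow(verdicts),
                      sum(verdicts$verdict == "constant-model")))

  correlations <- stage("correlations", {
    correlation_screen(sessions, config$cor_group_a, config$cor_group_b)
  })
  note("correlations", sprintf("%d pairs tested", nrow(correlations)))

  binned <- stage("binned_means", {
    res <- lapply(outcomes, function(oc) bin_by_two_days(sessions, oc))
    names(res) <- outcomes
    res
  })
  note("binned_means", sprintf("%d outcomes binned", length(binned)))

  log_tab <- do.call(rbind, log)
  report <- structure(
    list(config = config, sessions = sessions, lmm = lmm,
         verdicts = verdicts, correlations = correlations, binned = binned,
         log = log_tab),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    write_study_csv(study, file.path(out_dir, "study.csv"))
    write_study_csv(sessions, file.path(out_dir, "sessions.csv"))
    utils::write.csv(as.data.frame(verdicts), file.path(out_dir, "lmm_verdicts.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(correlations),
                     file.path(out_dir, "correlations.csv"), row.names = FALSE)
    binned_long <- do.call(rbind, lapply(names(binned), function(oc) {
      cbind(outcome = oc, as.data.frame(binned[[oc]]))
    }))
    utils::write.csv(binned_long, file.path(out_dir, "binned_means.csv"),
                     row.names = FALSE)
    lmm_json <- lapply(lmm, function(r) {
      list(beta_raw = as.list(r$fit$beta_raw),
           varcomp = as.list(r$fit$varcomp),
           sigma2_resid = r$fit$sigma2_resid,
           logLik_REML = r$fit$logLik_REML,
           F = r$test$F, df1 = r$test$df1, df2 = r$test$df2,
           p_value = r$test$p_value, verdict = r$test$verdict,
           coefficients = r$test$coefficients)
    })
    jsonlite::write_json(lmm_json, file.path(out_dir, "lmm_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    log_out <- rbind(log_tab,
                     tibble::tibble(stage = "meta",
                                    detail = sprintf("seed=%d R=%s", config$seed,
                                                     getRversion()),
                                    elapsed_s = NA))
    utils::write.csv(as.data.frame(log_out), file.path(out_dir, "run_log.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Synthetic cycle-study pipeline report\n")
  cat(sprintf("  %d subjects, %d sessions\n",
              length(unique(x$sessions$subject_id)), nrow(x$sessions)))
  cat("  combined-test verdicts:\n")
  print(as.data.frame(x$verdicts[, c("outcome", "F", "p_value", "verdict")]),
        digits = 3)
  sig <- x$correlations[x$correlations$significant, ]
  cat(sprintf("  correlation screen: %d/%d pairs significant at P <= 0.05\n",
              nrow(sig), nrow(x$correlations)))
  invisible(x)
}
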