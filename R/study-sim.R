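#' Longitudinal study design for the cycle simulator
#'
#' @param n_subjects Number of participants.
#' @param sessions Integer range `c(min, max)` of test sessions per subject;
#'   each subject is tested on that many distinct cycle days.
#' @param cycle_length_days Cycle length in days, a scalar or one value per
#'   subject.
#' @param start_date First possible menses onset in the study window.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_subjects = 9, sessions = c(12, 14),
                         cycle_length_days = 28,
                         start_date = as.Date("2017-05-01"), seed = 1L) {
  stopifnot(n_subjects >= 2, length(sessions) == 2, sessions[1] >= 2,
            sessions[2] >= sessions[1], all(cycle_length_days >= 21))
  if (any(sessions[2] > cycle_length_days)) {
    stop("more sessions than distinct cycle days")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions = as.integer(sessions),
                 cycle_length_days = as.integer(cycle_length_days),
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "study_design")
}

#' Outcome effect specification for the cycle simulator
#'
#' One outcome variable is generated as
#' `value = subject_baseline + cycle_effect(day) + noise`, where the
#' subject baseline is `baseline + N(0, subject_sd)`, the noise SD is
#' `noise_cv * subject_baseline` (a within-subject coefficient of
#' variation), and the cycle effect is evaluated on the allocated cycle day
#' (1..28).
#'
#' @param name Outcome (column) name.
#' @param baseline Population mean, in `unit`.
#' @param unit Measurement unit label.
#' @param subject_sd Between-subject SD, same unit.
#' @param noise_cv Within-subject coefficient of variation (fraction >= 0).
#' @param cycle One of [cycle_none()], [cycle_linear()], [cycle_sin()].
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(name, baseline, unit = "", subject_sd = 0,
                        noise_cv = 0, cycle = cycle_none()) {
  stopifnot(is.character(name), subject_sd >= 0, noise_cv >= 0,
            inherits(cycle, "cycle_effect"))
  structure(list(name = name, baseline = baseline, unit = unit,
                 subject_sd = subject_sd, noise_cv = noise_cv, cycle = cycle),
            class = "effect_spec")
}

#' Cycle-day effect shapes
#'
#' `cycle_none()` is a flat (null) effect; `cycle_linear()` adds
#' `slope * (day - 1)` per allocated cycle day; `cycle_sin()` adds a
#' sinusoid `amplitude * sin(2 * pi * (day - phase_day) / 28)` with
#' peak-to-trough range `2 * amplitude`.
#'
#' @param slope Change per cycle day (outcome units/day).
#' @param amplitude Sinusoid amplitude (outcome units).
#' @param phase_day Day offset of the sinusoid.
#' @return Object of class `cycle_effect`.
#' @export
cycle_none <- function() {
  structure(list(type = "none"), class = "cycle_effect")
}

#' @rdname cycle_none
#' @export
cycle_linear <- function(slope) {
  structure(list(type = "linear", slope = slope), class = "cycle_effect")
}

#' @rdname cycle_none
#' @export
cycle_sin <- function(amplitude, phase_day = 0) {
  structure(list(type = "sin", amplitude = amplitude, phase_day = phase_day),
            class = "cycle_effect")
}

eval_cycle_effect <- function(cycle, day) {
  switch(cycle$type,
    none = rep(0, length(day)),
    linear = cycle$slope * (day - 1),
    sin = cycle$amplitude * sin(2 * pi * (day - cycle$phase_day) / 28)
  )
}

#' Default body-composition outcome set
#'
#' Six bioimpedance outcomes with baselines matching a squad of well-trained
#' female athletes (body mass 61 kg, skeletal muscle 44.4% and fat 20.3% of
#' body mass, total body water partitioned into extra- and intracellular
#' compartments). Within-subject coefficients of variation use the
#' instrument repeatability figures for body mass (0.1%), skeletal muscle
#' mass (0.4%), total body water (1.0%), intracellular (0.3%) and
#' extracellular water (0.4%); fat mass, for which no instrument figure is
#' available, uses 4.8%, back-derived from an observed 3.8% mean individual
#' deviation via the folded-normal relation. All cycle effects default to
#' none (a null study).
#'
#' @param ecw_slope Optional linear cycle effect on extracellular water in
#'   l/day (e.g. 0.01 to plant the fluid-retention trend scenario).
#' @return Named list of [effect_spec()] objects.
#' @export
default_study_effects <- function(ecw_slope = 0) {
  ecw_cycle <- if (ecw_slope == 0) cycle_none() else cycle_linear(ecw_slope)
  specs <- list(
    effect_spec("BM", 61, "kg", subject_sd = 6, noise_cv = 0.001),
    effect_spec("SMM", 27.1, "kg", subject_sd = 3, noise_cv = 0.004),
    effect_spec("FM", 12.4, "kg", subject_sd = 2.5, noise_cv = 0.048),
    effect_spec("TBW", 35.5, "l", subject_sd = 3, noise_cv = 0.010),
    effect_spec("ECW", 13.5, "l", subject_sd = 1.2, noise_cv = 0.004,
                cycle = ecw_cycle),
    effect_spec("ICW", 22.0, "l", subject_sd = 2, noise_cv = 0.003)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Simulate a longitudinal cycle study table
#'
#' Each subject enters the study at a random point of their cycle, is
#' tested on `sessions` distinct cycle days (sampled without replacement),
#' and every outcome in `effects` is generated per session from its
#' baseline, subject random effect, cycle-day effect and multiplicative
#' measurement noise. Menses onset dates bracketing each test date are
#' recorded so that cycle-day allocation can be exercised downstream; the
#' allocated day (via [allocate_cycle_day()]) is included.
#'
#' @param design A [study_design()].
#' @param effects List of [effect_spec()] objects (see
#'   [default_study_effects()]).
#' @return A tibble of class `cycle_study`, one row per subject-session:
#'   `subject_id`, `session`, `test_date`, `menses_onset_prev`,
#'   `menses_onset_next`, `cycle_day`, then one column per outcome. The
#'   effect specification is attached as attribute `effects`.
#' @export
generate_cycle_dataset <- function(design = study_design(),
                                   effects = default_study_effects()) {
  stopifnot(inherits(design, "study_design"))
  stopifnot(all(vapply(effects, inherits, TRUE, "effect_spec")))
  L <- rep_len(design$cycle_length_days, design$n_subjects)
  with_local_seed(design$seed, {
    rows <- lapply(seq_len(design$n_subjects), function(i) {
      n_choices <- seq(design$sessions[1], design$sessions[2])
      n_i <- if (length(n_choices) == 1) n_choices else sample(n_choices, 1)
      raw_days <- sort(sample.int(L[i], n_i))
      onset_prev <- design$start_date + sample.int(28, 1) - 1
      onset_next <- onset_prev + L[i]
      tibble::tibble(
        subject_id = sprintf("S%02d", i),
        session = seq_len(n_i),
        test_date = onset_prev + raw_days - 1,
        menses_onset_prev = onset_prev,
        menses_onset_next = onset_next
      )
    })
    d <- do.call(rbind, rows)
    d$cycle_day <- allocate_cycle_day(d$test_date, d$menses_onset_prev,
                                      d$menses_onset_next)
    for (ef in effects) {
      base_i <- ef$baseline + stats::rnorm(design$n_subjects, 0, ef$subject_sd)
      bi <- base_i[match(d$subject_id, sprintf("S%02d", seq_len(design$n_subjects)))]
      d[[ef$name]] <- bi + eval_cycle_effect(ef$cycle, d$cycle_day) +
        stats::rnorm(nrow(d), 0, ef$noise_cv * bi)
    }
    structure(d, effects = effects, design = design,
              class = c("cycle_study", class(d)))
  })
}

#' Write / read a study table as CSV
#'
#' Columns `subject_id, session, test_date, menses_onset_prev,
#' menses_onset_next, cycle_day, <outcomes>` with ISO dates.
#'
#' @param data A `cycle_study` tibble (or compatible data frame).
#' @param path File path.
#' @return `write_study_csv()` returns `path` invisibly; `read_study_csv()`
#'   returns a tibble with `Date` columns restored.
#' @export
write_study_csv <- function(data, path) {
  d <- as.data.frame(data)
  for (cn in c("test_date", "menses_onset_prev", "menses_onset_next")) {
    if (cn %in% names(d)) d[[cn]] <- format(as.Date(d[[cn]]))
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("test_date", "menses_onset_prev", "menses_onset_next")) {
    if (cn %in% names(d)) d[[cn]] <- as.Date(d[[cn]])
  }
  tibble::as_tibble(d)
}
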