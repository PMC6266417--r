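#' Individual relative-deviation statistics
#'
#' For every subject, the relative deviation of each session from the
#' subject's own mean: `|value - subject mean| / subject mean * 100`.
#' Reported are the mean and SD over subjects of the per-subject mean
#' deviation, and the largest single-session deviation across all subjects
#' (the "maximum individual deviation").
#'
#' @param data Study table with a `subject_id` column.
#' @param outcome Outcome column name.
#' @return List: `mean_pct`, `sd_pct`, `max_pct`, and `per_subject`
#'   (tibble of per-subject mean deviations).
#' @export
deviation_stats <- function(data, outcome) {
  stopifnot(outcome %in% names(data), "subject_id" %in% names(data))
  v <- split(data[[outcome]], data$subject_id)
  ns <- vapply(v, length, 0L)
  if (any(ns < 2)) {
    stop("every subject needs at least 2 sessions; offending: ",
         paste(names(v)[ns < 2], collapse = ", "))
  }
  per <- vapply(v, function(x) {
    m <- mean(x)
    if (m == 0) stop("subject mean is zero; relative deviation undefined")
    mean(abs(x - m) / m) * 100
  }, numeric(1))
  mx <- max(vapply(v, function(x) {
    m <- mean(x)
    max(abs(x - m) / m) * 100
  }, numeric(1)))
  list(mean_pct = mean(per), sd_pct = stats::sd(per), max_pct = mx,
       per_subject = tibble::tibble(subject_id = names(per),
                                    mean_dev_pct = unname(per)))
}

#' Two-day binned means across the cycle
#'
#' Allocated cycle days are grouped into fourteen bins (days 1-2, 3-4, ...,
#' 27-28) and the outcome is averaged over all observations (all subjects
#' pooled) in each bin. Bins with no observations are reported with `NA`.
#'
#' @param data Study table with a `cycle_day` column.
#' @param outcome Outcome column name.
#' @return Tibble with `bin`, `day_lo`, `day_hi`, `n`, `mean`.
#' @export
bin_by_two_days <- function(data, outcome) {
  stopifnot(outcome %in% names(data), "cycle_day" %in% names(data))
  bin <- ceiling(data$cycle_day / 2)
  out <- tibble::tibble(bin = 1:14, day_lo = seq(1, 27, 2),
                        day_hi = seq(2, 28, 2))
  agg_n <- tapply(data[[outcome]], factor(bin, levels = 1:14), length)
  agg_m <- tapply(data[[outcome]], factor(bin, levels = 1:14), mean)
  out$n <- as.integer(ifelse(is.na(agg_n), 0L, agg_n))
  out$mean <- as.numeric(agg_m)
  out
}
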