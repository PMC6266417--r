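#' Allocate test dates to menstrual-cycle days
#'
#' Test days are retrospectively allocated to a day in the cycle, with day 1
#' the onset of menses and day 28 the day before the next onset. For an
#' observed cycle of length L != 28 days, the raw day is linearly rescaled
#' onto 1..28 and rounded: `day = round(1 + (d - 1) * 27 / (L - 1))` with
#' `d` the raw day since onset (1-based). With `normalize = "truncate"` the
#' raw day is used directly and capped at 28 instead.
#'
#' @param test_date,onset_prev,onset_next `Date` vectors (recycled): the
#'   test day, the most recent menses onset at or before it, and the next
#'   onset after it.
#' @param normalize How cycles different from 28 days map onto 1..28.
#' @return Integer vector of cycle days in 1..28.
#' @export
allocate_cycle_day <- function(test_date, onset_prev, onset_next,
                               normalize = c("rescale", "truncate")) {
  normalize <- match.arg(normalize)
  test_date <- as.Date(test_date)
  onset_prev <- as.Date(onset_prev)
  onset_next <- as.Date(onset_next)
  n <- max(length(test_date), length(onset_prev), length(onset_next))
  test_date <- rep_len(test_date, n)
  onset_prev <- rep_len(onset_prev, n)
  onset_next <- rep_len(onset_next, n)
  if (any(onset_next <= onset_prev)) {
    stop("onset_next must lie after onset_prev")
  }
  bad <- test_date < onset_prev | test_date >= onset_next
  if (any(bad)) {
    stop("test_date outside the recorded cycle: ",
         paste(format(test_date[bad]), collapse = ", "))
  }
  d <- as.integer(test_date - onset_prev) + 1L
  L <- as.integer(onset_next - onset_prev)
  day <- ifelse(L == 28L, d,
                if (normalize == "rescale") {
                  round(1 + (d - 1) * 27 / (L - 1))
                } else {
                  pmin(d, 28L)
                })
  as.integer(day)
}
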