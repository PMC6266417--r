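#' Pearson correlation with t-based test
#'
#' Sample Pearson correlation after pairwise deletion of missing values,
#' with the two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df (as in
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length.
#' @param var_a,var_b Optional variable names carried on the result.
#' @return One-row tibble of class `correlation_result`: `var_a`, `var_b`,
#'   `n`, `r`, `p`, `significant` (at P <= 0.05).
#' @export
pearson <- function(x, y, var_a = "x", var_b = "y") {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations; got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in ", if (stats::sd(x) == 0) var_a else var_b)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  out <- tibble::tibble(var_a = var_a, var_b = var_b, n = n,
                        r = unname(ct$estimate), p = ct$p.value,
                        significant = ct$p.value <= 0.05)
  class(out) <- c("correlation_result", class(out))
  out
}

#' Pairwise Pearson screen between two variable groups
#'
#' All pairs between `group_a` and `group_b` are correlated over the pooled
#' observations (all subjects and sessions; repeated measures are
#' deliberately ignored, and no multiplicity correction is applied -- the
#' number of tests is reported so readers can judge). With
#' `by_subject_mean = TRUE` each subject contributes one mean value per
#' variable instead.
#'
#' @param data Data frame holding the variables (and `subject_id` if
#'   `by_subject_mean`).
#' @param group_a,group_b Character vectors of column names.
#' @param by_subject_mean Collapse to per-subject means before correlating.
#' @return Tibble with one row per pair (`var_a`, `var_b`, `n`, `r`, `p`,
#'   `significant`), with the number of tests in attribute `n_tests`.
#' @export
correlation_screen <- function(data, group_a, group_b,
                               by_subject_mean = FALSE) {
  missing <- setdiff(c(group_a, group_b), names(data))
  if (length(missing) > 0) {
    stop("variable(s) not in data: ", paste(missing, collapse = ", "))
  }
  if (by_subject_mean) {
    stopifnot("subject_id" %in% names(data))
    vars <- unique(c(group_a, group_b))
    data <- do.call(rbind, lapply(split(data[vars], data$subject_id),
                                  function(d) as.data.frame(lapply(d, mean, na.rm = TRUE))))
  }
  rows <- list()
  for (a in group_a) for (b in group_b) {
    rows[[paste(a, b)]] <- pearson(data[[a]], data[[b]], var_a = a, var_b = b)
  }
  out <- do.call(rbind, rows)
  out <- tibble::as_tibble(out)
  attr(out, "n_tests") <- nrow(out)
  out
}
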