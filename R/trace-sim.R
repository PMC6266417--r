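# run code with a private RNG stream; the caller's RNG state is untouched
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulation parameters for a perturbation trial
#'
#' Describes a single balance-platform trial: quiet stance until the
#' perturbation is triggered (within the first 5 s of the trial), then a
#' damped oscillation `amplitude * exp(-damping * tau) * sin(2*pi*freq * tau)`
#' riding on Gaussian sway noise, recorded for `post_duration_s` seconds
#' after the perturbation at sampling rate `fs`.
#'
#' @param fs Sampling rate in Hz.
#' @param pert_time_s Perturbation onset in seconds, in (0, 5].
#' @param post_duration_s Recording length after the perturbation, seconds.
#' @param amplitude Oscillation amplitude, platform units.
#' @param damping Exponential decay rate, 1/s; must be positive.
#' @param freq Oscillation frequency, Hz.
#' @param noise_sd Gaussian sway noise SD, platform units.
#' @param y_gain Deterministic y-channel amplitude as a fraction of the x
#'   amplitude (perturbations act mostly along x).
#' @param seed Integer seed; all randomness in the trial flows from it.
#' @return Object of class `balance_sim_params`.
#' @export
balance_sim_params <- function(fs = 50, pert_time_s = 2, post_duration_s = 20,
                               amplitude = 10, damping = 0.4, freq = 1.5,
                               noise_sd = 0.05, y_gain = 0.6, seed = 1L) {
  stopifnot(fs > 0, pert_time_s > 0, pert_time_s <= 5, post_duration_s > 0,
            damping > 0, noise_sd >= 0, amplitude >= 0, freq > 0)
  structure(as.list(environment()), class = "balance_sim_params")
}

#' Construct a balance trace object
#'
#' @param time_s Strictly increasing uniform time grid, seconds.
#' @param x,y Platform displacement channels, platform units.
#' @param fs Sampling rate in Hz; must match the grid spacing.
#' @param pert_index Sample index (1-based) of perturbation onset.
#' @param leg,direction Trial annotation: supporting leg and perturbation
#'   direction.
#' @return Object of class `balance_trace`: tibble with columns `time_s`,
#'   `x`, `y` and attributes `fs`, `pert_index`, `leg`, `direction`.
#' @export
balance_trace <- function(time_s, x, y, fs, pert_index,
                          leg = c("left", "right"),
                          direction = c("medial", "lateral")) {
  leg <- match.arg(leg); direction <- match.arg(direction)
  n <- length(time_s)
  stopifnot(length(x) == n, length(y) == n, n >= 2)
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time grid must be strictly increasing")
  if (max(abs(fs * dt - 1)) > 1e-6) stop("fs does not match the time grid")
  if (pert_index < 1 || pert_index > n) stop("pert_index out of range")
  out <- tibble::tibble(time_s = time_s, x = x, y = y)
  structure(out, fs = fs, pert_index = as.integer(pert_index),
            leg = leg, direction = direction,
            class = c("balance_trace", class(out)))
}

#' Simulate a perturbation-response platform trace
#'
#' x(t) is Gaussian quiet-stance noise before the perturbation and a damped
#' sinusoid plus noise afterwards; y(t) carries the same deterministic
#' response scaled by `y_gain`, with independent noise. The perturbation
#' sample index is recorded on the trace.
#'
#' @param params A [balance_sim_params()] object.
#' @param leg,direction Trial annotation, carried through to the trace.
#' @return A [balance_trace()].
#' @export
generate_balance_trace <- function(params, leg = "left", direction = "medial") {
  stopifnot(inherits(params, "balance_sim_params"))
  p <- params
  n <- round((p$pert_time_s + p$post_duration_s) * p$fs) + 1L
  time_s <- (seq_len(n) - 1L) / p$fs
  pert_index <- round(p$pert_time_s * p$fs) + 1L
  tau <- pmax(time_s - time_s[pert_index], 0)
  resp <- p$amplitude * exp(-p$damping * tau) * sin(2 * pi * p$freq * tau)
  resp[seq_len(pert_index - 1L)] <- 0
  with_local_seed(p$seed, {
    x <- resp + stats::rnorm(n, 0, p$noise_sd)
    y <- p$y_gain * resp + stats::rnorm(n, 0, p$noise_sd)
    balance_trace(time_s, x, y, fs = p$fs, pert_index = pert_index,
                  leg = leg, direction = direction)
  })
}

#' Write / read a balance trace as CSV
#'
#' The file has comment header lines `# fs=`, `# pert_index=`, `# leg=`,
#' `# direction=` followed by a `time_s,x,y` table.
#'
#' @param trace A `balance_trace`.
#' @param path File path.
#' @return `write_balance_trace()` returns `path` invisibly;
#'   `read_balance_trace()` returns a `balance_trace`.
#' @export
write_balance_trace <- function(trace, path) {
  stopifnot(inherits(trace, "balance_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%s", attr(trace, "fs")),
    sprintf("# pert_index=%d", attr(trace, "pert_index")),
    sprintf("# leg=%s", attr(trace, "leg")),
    sprintf("# direction=%s", attr(trace, "direction"))
  ), con)
  utils::write.table(as.data.frame(trace)[, c("time_s", "x", "y")], con,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_balance_trace
#' @export
read_balance_trace <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  kv <- strsplit(sub("^# ", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  d <- utils::read.csv(path, comment.char = "#")
  balance_trace(d$time_s, d$x, d$y,
                fs = as.numeric(meta[["fs"]]),
                pert_index = as.integer(meta[["pert_index"]]),
                leg = meta[["leg"]], direction = meta[["direction"]])
}
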