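#' Build design matrices for the biquadratic random-coefficient model
#'
#' The model for outcome y of subject i at cycle day t is a quartic
#' polynomial with population coefficients and per-subject random
#' coefficients:
#' `y_im = sum_k (beta_k + b_ik) * t'^k + eps_im`, k = 0..4,
#' where `t' = (t - center) / scale` is the centred and scaled cycle day.
#' Raw day powers up to day^4 (about 6.1e5 at day 28) destroy the
#' conditioning of the normal equations, so the model is fitted on `t'` and
#' the coefficients are mapped back to the raw-day scale for reporting via
#' the triangular basis-change matrix returned as `A`
#' (`beta_raw = A %*% beta_scaled`).
#'
#' @param data Data frame with the outcome, a subject identifier and a
#'   cycle-day column.
#' @param outcome Name of the outcome column.
#' @param fixed_orders Polynomial orders of the fixed part (default 0:4,
#'   the biquadratic model with constant, linear, squared and cubic terms).
#' @param re_orders Polynomial orders receiving per-subject random
#'   coefficients; `integer(0)` drops all random effects.
#' @param day_col,subject_col Column names.
#' @param center,scale Day standardization constants; the defaults map
#'   days 1..28 onto \[-1, 1\].
#' @return Object of class `lmm_design`.
#' @export
build_design <- function(data, outcome, fixed_orders = 0:4, re_orders = 0:4,
                         day_col = "cycle_day", subject_col = "subject_id",
                         center = 14.5, scale = 13.5) {
  stopifnot(outcome %in% names(data), day_col %in% names(data),
            subject_col %in% names(data))
  y <- data[[outcome]]
  t_raw <- data[[day_col]]
  subject <- factor(data[[subject_col]])
  ok <- stats::complete.cases(y, t_raw, subject)
  y <- y[ok]; t_raw <- t_raw[ok]; subject <- droplevels(subject[ok])
  if (nlevels(subject) < 2) stop("need at least 2 subjects")
  if (length(unique(t_raw)) < length(fixed_orders)) {
    stop("need at least ", length(fixed_orders), " distinct days; got ",
         length(unique(t_raw)))
  }
  ts <- (t_raw - center) / scale
  X <- vapply(fixed_orders, function(k) ts^k, numeric(length(ts)))
  colnames(X) <- paste0("t", fixed_orders)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("rank-deficient fixed design; deficient column(s): ",
         paste(bad, collapse = ", "))
  }
  stopifnot(all(re_orders %in% fixed_orders))
  # basis change: coefficient of t^j in ((t - c)/s)^k
  p <- max(fixed_orders)
  A <- matrix(0, p + 1, p + 1)
  for (k in 0:p) for (j in 0:k) {
    A[j + 1, k + 1] <- choose(k, j) * (-center)^(k - j) / scale^k
  }
  A <- A[fixed_orders + 1, fixed_orders + 1, drop = FALSE]
  structure(
    list(y = y, X = X, subject = subject, t_raw = t_raw, t_scaled = ts,
         fixed_orders = fixed_orders, re_orders = re_orders,
         center = center, scale = scale, A = A, outcome = outcome),
    class = "lmm_design"
  )
}

# per-subject sufficient statistics: crossproducts of [X, y]
subject_stats <- function(design) {
  lapply(split(seq_along(design$y), design$subject), function(ix) {
    Xi <- design$X[ix, , drop = FALSE]
    yi <- design$y[ix]
    list(XtX = crossprod(Xi), Xty = crossprod(Xi, yi),
         yty = sum(yi^2), m = length(ix))
  })
}

# -2 * REML log-likelihood and GLS pieces for log-variance vector th
# th = c(log re variances (length q), log residual variance)
reml_pieces <- function(th, stats_list, re_idx, p) {
  q <- length(re_idx)
  s2 <- exp(th[q + 1])
  g <- if (q > 0) sqrt(exp(th[seq_len(q)])) else numeric(0)
  Sxx <- matrix(0, p, p); Sxy <- numeric(p); Syy <- 0; ld <- 0; n <- 0
  for (st in stats_list) {
    n <- n + st$m
    if (q > 0) {
      ZtZ <- st$XtX[re_idx, re_idx, drop = FALSE]
      W <- (g %o% g) * ZtZ
      Ks <- s2 * diag(q) + W
      ch <- tryCatch(chol(Ks), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      ld <- ld + (st$m - q) * log(s2) + 2 * sum(log(diag(ch)))
      # B = G K^{-1} G with K = s2 I + W
      B <- (g %o% g) * chol2inv(ch)
      XtZ <- st$XtX[, re_idx, drop = FALSE]
      Zty <- st$Xty[re_idx, , drop = FALSE]
      Sxx <- Sxx + (st$XtX - XtZ %*% B %*% t(XtZ)) / s2
      Sxy <- Sxy + (st$Xty - XtZ %*% B %*% Zty) / s2
      Syy <- Syy + (st$yty - crossprod(Zty, B %*% Zty)[1]) / s2
    } else {
      ld <- ld + st$m * log(s2)
      Sxx <- Sxx + st$XtX / s2
      Sxy <- Sxy + st$Xty / s2
      Syy <- Syy + st$yty / s2
    }
  }
  chS <- tryCatch(chol(Sxx), error = function(e) NULL)
  if (is.null(chS)) return(NULL)
  beta <- backsolve(chS, forwardsolve(t(chS), Sxy))
  quad <- Syy - sum(beta * Sxy)
  m2l <- ld + 2 * sum(log(diag(chS))) + quad + (n - p) * log(2 * pi)
  list(m2l = as.numeric(m2l), beta = as.numeric(beta), Sxx = Sxx,
       chS = chS, n = n)
}

#' Fit the random-coefficient model by restricted maximum likelihood
#'
#' Variance components (one variance per random polynomial order, i.e. a
#' diagonal random-effect covariance, plus the residual variance) are
#' estimated by maximizing the restricted likelihood with a bounded
#' quasi-Newton search on the log-variance scale; fixed effects are then
#' the generalized least-squares solution at the optimum. The diagonal
#' random-effect structure is deliberate: with few subjects an unstructured
#' 5 x 5 covariance is not identifiable. Per-subject computations use the
#' Woodbury identity on the subject cross-products, so the cost per
#' likelihood evaluation is O(subjects) 5 x 5 factorizations regardless of
#' the number of sessions.
#'
#' @param design An [build_design()] object.
#' @param start_frac Starting value of every variance component as a
#'   fraction of the outcome variance.
#' @return Object of class `lmm_fit`: fixed effects on the scaled
#'   (`beta`) and raw day (`beta_raw`) scales with covariances, random
#'   variance components `varcomp` (named `sigma2_b<k>`), residual variance
#'   `sigma2_resid`, REML log-likelihood, convergence info (message,
#'   iterations, boundary flags) and the design.
#' @export
fit_reml <- function(design, start_frac = 0.1) {
  stopifnot(inherits(design, "lmm_design"))
  stats_list <- subject_stats(design)
  p <- ncol(design$X)
  re_idx <- match(design$re_orders, design$fixed_orders)
  q <- length(re_idx)
  vy <- stats::var(design$y)
  if (!is.finite(vy) || vy <= 0) vy <- max(mean(design$y^2), 1e-12)
  start <- rep(log(start_frac * vy), q + 1)
  lo <- rep(log(1e-10 * vy), q + 1)
  hi <- rep(log(1e4 * vy), q + 1)
  obj <- function(th) {
    pc <- reml_pieces(th, stats_list, re_idx, p)
    if (is.null(pc) || !is.finite(pc$m2l)) return(1e10)
    pc$m2l
  }
  opt <- stats::nlminb(start, obj, lower = lo, upper = hi,
                       control = list(iter.max = 500, eval.max = 1000))
  if (!opt$convergence %in% c(0, 1) || !is.finite(opt$objective) ||
      opt$objective >= 1e10) {
    stop("REML did not converge: ", opt$message,
         " (", opt$iterations, " iterations, objective ",
         format(opt$objective), ")")
  }
  pc <- reml_pieces(opt$par, stats_list, re_idx, p)
  vc <- exp(opt$par)
  boundary <- vc <= 1e-8 * vy
  varcomp <- if (q > 0) {
    stats::setNames(vc[seq_len(q)], paste0("sigma2_b", design$re_orders))
  } else numeric(0)
  cov_beta <- chol2inv(pc$chS)
  dimnames(cov_beta) <- list(colnames(design$X), colnames(design$X))
  beta <- stats::setNames(pc$beta, colnames(design$X))
  beta_raw <- stats::setNames(as.numeric(design$A %*% pc$beta),
                              paste0("day^", design$fixed_orders))
  cov_beta_raw <- design$A %*% cov_beta %*% t(design$A)
  dimnames(cov_beta_raw) <- list(names(beta_raw), names(beta_raw))
  structure(
    list(beta = beta, beta_raw = beta_raw,
         cov_beta = cov_beta, cov_beta_raw = cov_beta_raw,
         varcomp = varcomp, sigma2_resid = vc[q + 1],
         logLik_REML = -opt$objective / 2,
         n = pc$n, p = p,
         convergence = list(code = opt$convergence, message = opt$message,
                            iterations = opt$iterations,
                            boundary = boundary),
         design = design),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-coefficient polynomial model (REML)\n")
  cat(sprintf("  outcome: %s, n = %d obs, %d subjects\n", x$design$outcome,
              x$n, nlevels(x$design$subject)))
  cat("  fixed effects (raw day scale):\n")
  print(signif(x$beta_raw, 4))
  if (length(x$varcomp) > 0) {
    cat("  random-effect variances (scaled basis):\n")
    print(signif(x$varcomp, 4))
  }
  cat(sprintf("  residual variance: %s, REML logLik: %.3f\n",
              format(signif(x$sigma2_resid, 4)), x$logLik_REML))
  invisible(x)
}

#' Combined and per-coefficient tests of the time-dependent terms
#'
#' The combined hypothesis `beta_1 = beta_2 = beta_3 = beta_4 = 0` (all
#' non-constant polynomial terms zero) is tested with an F statistic built
#' from the fitted generalized-least-squares covariance of the fixed
#' effects, with numerator df equal to the number of non-constant terms and
#' denominator df `n - p` (residual df). If the combined test is not
#' significant the model reduces to the constant term, i.e. the outcome
#' shows no time dependence across the cycle. Per-coefficient Wald t-tests
#' are reported on the raw day scale.
#'
#' @param fit An [fit_reml()] object.
#' @param alpha Significance level for the verdict.
#' @return Object of class `coef_test`: `F`, `df1`, `df2`, `p_value`,
#'   `verdict` (`"time-dependent"` iff `p_value <= alpha`, else
#'   `"constant-model"`), and `coefficients` (tibble with raw-scale
#'   estimate, SE, t, p per coefficient).
#' @export
test_coefficients <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lmm_fit"))
  nc <- which(fit$design$fixed_orders != 0)
  if (length(nc) == 0) stop("no non-constant terms to test")
  cb <- fit$beta[nc]
  V <- fit$cov_beta[nc, nc, drop = FALSE]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps) * max(diag(ch)))) {
    stop("singular contrast covariance; combined test unavailable")
  }
  r <- length(nc)
  Fstat <- sum(backsolve(ch, cb, transpose = TRUE)^2) / r
  df2 <- fit$n - fit$p
  pval <- stats::pf(Fstat, r, df2, lower.tail = FALSE)
  se_raw <- sqrt(diag(fit$cov_beta_raw))
  tt <- fit$beta_raw / se_raw
  coefs <- tibble::tibble(
    term = names(fit$beta_raw),
    estimate = as.numeric(fit$beta_raw),
    se = se_raw,
    t = tt,
    p = 2 * stats::pt(abs(tt), df2, lower.tail = FALSE)
  )
  structure(
    list(F = Fstat, df1 = r, df2 = df2, p_value = pval,
         verdict = if (pval <= alpha) "time-dependent" else "constant-model",
         alpha = alpha, coefficients = coefs),
    class = "coef_test"
  )
}

#' @export
print.coef_test <- function(x, ...) {
  cat(sprintf("Combined test of time-dependent terms: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p_value))
  cat("  verdict:", x$verdict, "\n")
  print(x$coefficients)
  invisible(x)
}

#' Fit and test one outcome of a cycle study
#'
#' Convenience wrapper: [build_design()], [fit_reml()],
#' [test_coefficients()].
#'
#' @param data Study table with `subject_id` and `cycle_day` columns.
#' @param outcome Outcome column name.
#' @param ... Passed to [build_design()].
#' @param alpha Significance level.
#' @return List with elements `fit` and `test`.
#' @export
fit_cycle_lmm <- function(data, outcome, ..., alpha = 0.05) {
  design <- build_design(data, outcome, ...)
  fit <- fit_reml(design)
  list(fit = fit, test = test_coefficients(fit, alpha = alpha))
}
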