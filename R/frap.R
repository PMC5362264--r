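# FRAP analysis: pre-bleach normalization, pointwise averaging across
# membrane sheets, and nonlinear least-squares fitting of the hyperbolic
# recovery model y(t) = offset + M * t / (t + t_half).

#' Construct a normalized FRAP recovery trace
#'
#' A tibble of class `recovery_trace` with columns `time` (s, relative to
#' the first post-bleach frame, strictly increasing, starting at 0) and
#' `value` (intensity normalized so the pre-bleach mean is 1).
#'
#' @param time post-bleach times (s), `time[1] = 0`
#' @param value normalized intensities
#' @param prebleach_mean pre-bleach mean on the same normalized scale
#' @param background background used during normalization
#' @param n_prebleach number of pre-bleach frames used
#' @return a `recovery_trace` tibble
#' @export
recovery_trace <- function(time, value, prebleach_mean = 1, background = 0,
                           n_prebleach = 3L) {
  check_that(length(time) == length(value) && length(time) >= 1,
             "`time` and `value` must have equal positive length")
  check_that(abs(time[1]) < 1e-9, "times must be relative to the first post-bleach frame (time[1] = 0)")
  check_that(all(diff(time) > 0), "`time` must be strictly increasing")
  out <- tibble(time = as.numeric(time), value = as.numeric(value))
  class(out) <- c("recovery_trace", class(out))
  attr(out, "prebleach_mean") <- prebleach_mean
  attr(out, "background") <- background
  attr(out, "n_prebleach") <- as.integer(n_prebleach)
  out
}

#' Normalize raw FRAP frames to the pre-bleach level
#'
#' Background-subtracts the raw intensities and divides by the
#' background-subtracted mean of the pre-bleach frames. The pre-bleach
#' frames are consumed by the normalization and excluded from the
#' returned trace; post-bleach times are re-expressed relative to the
#' first post-bleach frame.
#'
#' @param frames data frame of raw frames with columns `time` and
#'   `intensity`, pre-bleach frames first (as produced by
#'   [simulate_frap_trace()]`$raw`, or read from a two-column table)
#' @param background background intensity to subtract (>= 0)
#' @param n_prebleach number of leading pre-bleach frames (>= 3)
#' @return a [recovery_trace()]
#' @export
normalize_recovery <- function(frames, background = 0, n_prebleach = 3) {
  check_that(is.data.frame(frames) &&
               all(c("time", "intensity") %in% names(frames)),
             "`frames` must have columns `time` and `intensity`")
  check_that(is_number(background) && background >= 0,
             "`background` must be >= 0")
  n_pre <- as.integer(n_prebleach)
  check_that(n_pre >= 3, "at least 3 pre-bleach frames are required, got %d", n_pre)
  check_that(nrow(frames) > n_pre,
             "no post-bleach frames after the %d pre-bleach frames", n_pre)
  pre <- frames$intensity[seq_len(n_pre)]
  prebleach_mean <- mean(pre)
  if (prebleach_mean <= background) {
    abort(sprintf(
      "pre-bleach mean (%.3g) does not exceed background (%.3g); trace uninterpretable",
      prebleach_mean, background))
  }
  post <- frames[-seq_len(n_pre), ]
  value <- (post$intensity - background) / (prebleach_mean - background)
  recovery_trace(post$time - post$time[1], value,
                 prebleach_mean = prebleach_mean, background = background,
                 n_prebleach = n_pre)
}

#' Average recovery traces pointwise
#'
#' Traces must share a time base (equal frame interval); they are trimmed
#' to the shortest common length and averaged per time point.
#'
#' @param traces a list of [recovery_trace()]s (or data frames with
#'   `time`/`value`)
#' @return tibble with columns `time`, `mean`, `sd`, `n`, of class
#'   `recovery_trace` aliasing `value = mean` for direct fitting
#' @export
average_recovery <- function(traces) {
  check_that(is.list(traces) && length(traces) >= 1 &&
               all(vapply(traces, is.data.frame, TRUE)),
             "`traces` must be a non-empty list of recovery traces")
  n_min <- min(vapply(traces, nrow, 1L))
  times <- lapply(traces, function(tr) tr$time[seq_len(n_min)])
  base <- times[[1]]
  same <- vapply(times, function(t) isTRUE(all.equal(t, base, tolerance = 1e-8)),
                 TRUE)
  if (!all(same)) {
    abort("traces do not share a time base (mismatched frame rates); cannot average")
  }
  vals <- vapply(traces, function(tr) tr$value[seq_len(n_min)],
                 numeric(n_min))
  vals <- matrix(vals, nrow = n_min)
  out <- tibble(time = base,
                value = rowMeans(vals),
                sd = apply(vals, 1, stats::sd),
                n = length(traces))
  class(out) <- c("recovery_trace", class(out))
  attr(out, "n_traces") <- length(traces)
  out
}

#' Fit the hyperbolic recovery model
#'
#' Fits `y(t) = offset + M * t / (t + t_half)` to a normalized recovery
#' trace by nonlinear least squares (Levenberg-Marquardt), yielding the
#' half time of recovery `t_half`. Initialization: `offset` = first
#' value, `M` = last - first, `t_half` = first time the trace exceeds
#' `offset + M/2` (fallback: mid-time). Box constraints keep the
#' optimizer out of degenerate plateaus: `offset`, `M` in `[0, 1.5]`,
#' `t_half` in `(0, 10 * max(t)]`.
#'
#' @param trace a [recovery_trace()] (or data frame with `time`, `value`),
#'   with at least 5 post-bleach points
#' @return an object of class `frap_fit` with elements `offset`,
#'   `recovery`, `t_half`, `rss`, `converged`, `fit` (the underlying nls
#'   object) and `trace`
#' @seealso [tidy.frap_fit()], [glance.frap_fit()], [autoplot.frap_fit()]
#' @export
fit_hyperbola <- function(trace) {
  check_that(is.data.frame(trace) && all(c("time", "value") %in% names(trace)),
             "`trace` must have columns `time` and `value`")
  check_that(nrow(trace) >= 5, "need >= 5 post-bleach points, got %d", nrow(trace))
  t <- trace$time
  y <- trace$value
  if (stats::sd(y) == 0) {
    abort("all-constant trace: t_half is unidentifiable")
  }
  offset0 <- max(y[1], 0)
  m0 <- max(y[length(y)] - y[1], 1e-3)
  above <- which(y > offset0 + m0 / 2 & t > 0)
  t_half0 <- if (length(above) > 0) t[above[1]] else max(t) / 2
  t_half0 <- min(max(t_half0, 1e-3), 10 * max(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ offset + recovery * time / (time + t_half),
      data = data.frame(time = t, value = y),
      start = list(offset = offset0, recovery = m0, t_half = t_half0),
      lower = c(offset = 0, recovery = 0, t_half = 1e-9),
      upper = c(offset = 1.5, recovery = 1.5, t_half = 10 * max(t)),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warn(sprintf("hyperbola fit did not converge: %s", conditionMessage(fit)))
    return(structure(list(offset = NA_real_, recovery = NA_real_,
                          t_half = NA_real_, rss = NA_real_,
                          converged = FALSE, fit = NULL,
                          trace = as_tibble(trace[c("time", "value")])),
                     class = "frap_fit"))
  }
  cf <- coef(fit)
  structure(list(offset = unname(cf["offset"]),
                 recovery = unname(cf["recovery"]),
                 t_half = unname(cf["t_half"]),
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 fit = fit,
                 trace = as_tibble(trace[c("time", "value")])),
            class = "frap_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit> hyperbolic recovery y(t) = offset + M t / (t + t_half)\n")
  if (!x$converged) cat("  ** fit did not converge **\n")
  cat(sprintf("  offset = %.4f, M = %.4f, t_half = %.3f s, RSS = %.4g (n = %d)\n",
              x$offset, x$recovery, x$t_half, x$rss, nrow(x$trace)))
  invisible(x)
}

#' Broom-style methods for FRAP fits
#'
#' `tidy()` returns one row per parameter with standard errors from the
#' nls fit; `glance()` returns a one-row model summary; `predict()`
#' evaluates the fitted hyperbola.
#'
#' @param x,object a [fit_hyperbola()] result
#' @param ... unused
#' @return a tibble (`tidy`, `glance`) or numeric vector (`predict`)
#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  if (!x$converged || is.null(x$fit)) {
    return(tibble(term = c("offset", "recovery", "t_half"),
                  estimate = c(x$offset, x$recovery, x$t_half),
                  std.error = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"])
}

#' @rdname tidy.frap_fit
#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(offset = x$offset, recovery = x$recovery, t_half = x$t_half,
         rss = x$rss, n = nrow(x$trace), converged = x$converged)
}

#' @rdname tidy.frap_fit
#' @param newdata optional data frame with a `time` column
#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$trace$time else newdata$time
  hyperbola_model(t, object$offset, object$recovery, object$t_half)
}

# tidy()/glance() generics come from the generics package (as in broom)
#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
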