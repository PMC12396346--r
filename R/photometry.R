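#' Fiber-photometry trace
#'
#' Container for a raw fluorescence time series: sample times (strictly
#' increasing, seconds), fluorescence values (arbitrary units), the
#' sampling rate, an optional baseline window and optional stimulus onset
#' times. The sampling rate, when supplied, must agree with the median
#' sampling interval within 1%.
#'
#' @param t numeric times in seconds, strictly increasing.
#' @param F numeric fluorescence values, same length as `t`.
#' @param fs sampling rate in Hz; inferred from the median interval when
#'   `NULL`.
#' @param baseline_window `c(t0, t1)` in seconds, within the trace span.
#' @param stim_onsets optional numeric stimulus onset times (seconds).
#' @return an object of class `PhotometryTrace`.
#' @export
photometry_trace <- function(t, F, fs = NULL, baseline_window = NULL,
                             stim_onsets = NULL) {
  assert_that(is.numeric(t) && is.numeric(F) && length(t) == length(F),
              "t and F must be numeric vectors of equal length")
  assert_that(length(t) >= 2 && all(diff(t) > 0),
              "t must be strictly increasing with >= 2 samples")
  dt <- median(diff(t))
  if (is.null(fs)) {
    fs <- 1 / dt
  } else {
    assert_that(is_number(fs) && fs > 0, "fs must be a positive number")
    assert_that(abs(fs - 1 / dt) <= 0.01 * fs,
                "fs inconsistent with the median sampling interval")
  }
  if (!is.null(baseline_window)) {
    assert_that(length(baseline_window) == 2 &&
                  baseline_window[1] < baseline_window[2] &&
                  baseline_window[1] >= t[1] &&
                  baseline_window[2] <= t[length(t)],
                "baseline_window must be (t0, t1) within the trace span")
  }
  if (!is.null(stim_onsets)) {
    assert_that(all(stim_onsets >= t[1] & stim_onsets <= t[length(t)]),
                "stim_onsets must lie within the trace span")
  }
  structure(list(t = as.numeric(t), F = as.numeric(F), fs = fs,
                 baseline_window = baseline_window,
                 stim_onsets = stim_onsets),
            class = "PhotometryTrace")
}

#' @export
print.PhotometryTrace <- function(x, ...) {
  cat(sprintf("PhotometryTrace: %d samples, %.4g s span, fs = %.4g Hz\n",
              length(x$t), diff(range(x$t)), x$fs))
  invisible(x)
}

mono_exp <- function(t, p) p[["A"]] * exp(-t / p[["tau"]]) + p[["C"]]
bi_exp <- function(t, p) {
  p[["A1"]] * exp(-t / p[["tau1"]]) + p[["A2"]] * exp(-t / p[["tau2"]]) +
    p[["C"]]
}

# corrected AIC from RSS; k counts the error variance as a parameter
aicc_from_rss <- function(rss, n, k) {
  rss <- max(rss, 1e-300)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

fit_exp_optim <- function(t, F, start, fun) {
  # optimize over log(tau) to keep time constants positive
  taus <- grep("^tau", names(start), value = TRUE)
  tr <- function(p) { p[taus] <- exp(p[taus]); p }
  p0 <- start
  p0[taus] <- log(start[taus])
  obj <- function(p) sum((F - fun(t, tr(p)))^2)
  fit <- optim(p0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit2 <- optim(fit$par, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
  best <- if (fit2$value < fit$value) fit2 else fit
  list(par = tr(best$par), rss = best$value)
}

# Levenberg-damped Gauss-Newton refinement with analytic Jacobians,
# iterated to machine precision so the solution does not inherit the
# generic optimizer's stopping tolerance
gn_polish <- function(p, t, F, model, tau_max, max_iter = 60) {
  fun <- if (model == "mono") mono_exp else bi_exp
  jac <- function(p) {
    if (model == "mono") {
      e <- exp(-t / p[["tau"]])
      cbind(A = e, tau = p[["A"]] * t * e / p[["tau"]]^2, C = 1)
    } else {
      e1 <- exp(-t / p[["tau1"]]); e2 <- exp(-t / p[["tau2"]])
      cbind(A1 = e1, tau1 = p[["A1"]] * t * e1 / p[["tau1"]]^2,
            A2 = e2, tau2 = p[["A2"]] * t * e2 / p[["tau2"]]^2, C = 1)
    }
  }
  taus <- grep("^tau", names(p))
  lambda <- 1e-10
  rss <- sum((F - fun(t, as.list(p)))^2)
  for (it in seq_len(max_iter)) {
    r <- F - fun(t, as.list(p))
    J <- jac(p)
    H <- crossprod(J)
    step <- tryCatch(
      solve(H + lambda * diag(diag(H)), crossprod(J, r)),
      error = function(e) NULL)
    if (is.null(step)) break
    cand <- p + step[, 1]
    cand[taus] <- pmin(pmax(cand[taus], 1e-9), tau_max)
    rss_new <- sum((F - fun(t, as.list(cand)))^2)
    if (is.finite(rss_new) && rss_new <= rss) {
      moved <- max(abs(cand - p) / pmax(abs(p), 1e-12))
      p <- cand
      rss <- rss_new
      lambda <- max(lambda / 4, 1e-12)
      if (moved < 1e-13) break
    } else {
      lambda <- lambda * 10
      if (lambda > 1e6) break
    }
  }
  p
}

fit_exp_model <- function(t, F, model) {
  n <- length(t)
  span <- t[n] - t[1]
  drop <- F[1] - F[n]
  if (model == "mono") {
    start <- c(A = drop, tau = span / 3, C = F[n])
    fun <- mono_exp
    k <- 4
  } else {
    start <- c(A1 = drop / 2, tau1 = span / 10,
               A2 = drop / 2, tau2 = span / 2, C = F[n])
    fun <- bi_exp
    k <- 6
  }
  # nls first (fast, precise); deterministic optim fallback on failure
  par <- tryCatch({
    form <- if (model == "mono") {
      F ~ A * exp(-t / tau) + C
    } else {
      F ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2) + C
    }
    lower <- start
    lower[] <- -Inf
    lower[grep("^tau", names(start))] <- 1e-9
    # cap time constants at 10x the span: slower decay is unidentifiable
    # against the offset and leaves a degenerate fit valley
    upper <- start
    upper[] <- Inf
    upper[grep("^tau", names(start))] <- 10 * span
    ctrl <- stats::nls.control(maxiter = 200, warnOnly = FALSE)
    ft <- nls(form, data = list(t = t, F = F), start = as.list(start),
              algorithm = "port", lower = lower, upper = upper,
              control = ctrl)
    p <- gn_polish(coef(ft), t, F, model, tau_max = 10 * span)
    list(par = p, rss = sum((F - fun(t, as.list(p)))^2))
  }, error = function(e) NULL)
  if (is.null(par)) {
    par <- tryCatch({
      fo <- fit_exp_optim(t, F, start, fun)
      p <- gn_polish(fo$par, t, F, model, tau_max = 10 * span)
      list(par = p, rss = sum((F - fun(t, as.list(p)))^2))
    }, error = function(e) NULL)
  }
  if (is.null(par) || any(!is.finite(par$par))) return(NULL)
  if (model == "bi" && par$par[["tau1"]] > par$par[["tau2"]]) {
    par$par <- c(A1 = par$par[["A2"]], tau1 = par$par[["tau2"]],
                 A2 = par$par[["A1"]], tau2 = par$par[["tau1"]],
                 C = par$par[["C"]])
  }
  list(model = model, params = par$par, rss = par$rss, k = k,
       aicc = aicc_from_rss(par$rss, n, k))
}

#' Fit a photobleaching decay model
#'
#' Fits both a mono-exponential `A*exp(-t/tau) + C` and a bi-exponential
#' `A1*exp(-t/tau1) + A2*exp(-t/tau2) + C` to the raw trace by nonlinear
#' least squares (deterministic initialization: amplitude from the
#' first-to-last drop, offset from the final value, time constants from
#' fractions of the span) and keeps the model with the lower corrected
#' AIC. Bi-exponential time constants are stored in canonical order
#' `tau1 <= tau2`. A near-constant trace short-circuits to a mono fit
#' with zero amplitude.
#'
#' @param trace a [photometry_trace()].
#' @param model `"auto"` (AICc selection, default), `"mono"` or `"bi"`.
#' @return an object of class `BleachFit`: list with `model`, `params`,
#'   `rss`, `aicc`.
#' @export
fit_bleach <- function(trace, model = c("auto", "mono", "bi")) {
  assert_that(inherits(trace, "PhotometryTrace"), "trace must be a PhotometryTrace")
  model <- match.arg(model)
  t <- trace$t; F <- trace$F
  assert_that(length(t) >= 20, "need >= 20 samples to fit a bleach model")
  if (sd(F) < 1e-12 * max(1, abs(mean(F)))) {
    fit <- list(model = "mono",
                params = c(A = 0, tau = (t[length(t)] - t[1]) / 3,
                           C = mean(F)),
                rss = sum((F - mean(F))^2))
    fit$aicc <- aicc_from_rss(fit$rss, length(t), 4)
    return(structure(fit, class = "BleachFit"))
  }
  # fit on the standardized trace so results are exactly equivariant under
  # affine rescaling F -> aF + b (a > 0); parameters are mapped back after
  mF <- mean(F); sF <- sd(F)
  Fn <- (F - mF) / sF
  rescale <- function(fit) {
    if (is.null(fit)) return(NULL)
    amps <- grep("^A", names(fit$params))
    fit$params[amps] <- fit$params[amps] * sF
    fit$params[["C"]] <- fit$params[["C"]] * sF + mF
    fit$rss <- fit$rss * sF^2
    fit$aicc <- aicc_from_rss(fit$rss, length(t), fit$k)
    fit
  }
  fits <- list()
  if (model %in% c("auto", "mono")) {
    fits$mono <- rescale(fit_exp_model(t, Fn, "mono"))
  }
  if (model %in% c("auto", "bi")) {
    fits$bi <- rescale(fit_exp_model(t, Fn, "bi"))
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) {
    abort("bleach fit failed to converge for all requested models")
  }
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  best <- fits[[which.min(aicc)]]  # ties resolve to mono (listed first)
  structure(best, class = "BleachFit")
}

#' @export
print.BleachFit <- function(x, ...) {
  cat(sprintf("BleachFit (%s): %s; RSS = %.4g, AICc = %.4g\n", x$model,
              paste(names(x$params), signif(x$params, 4), sep = "=",
                    collapse = ", "), x$rss, x$aicc))
  invisible(x)
}

predict_bleach <- function(fit, t) {
  if (fit$model == "mono") mono_exp(t, fit$params) else bi_exp(t, fit$params)
}

#' Remove the fitted bleach curve from a trace
#'
#' Subtracts the fitted decay curve, leaving the offset-free fluctuation
#' series on which baseline z-scoring operates. Subtraction (rather than
#' division) is used; the subsequent z-score renders the two equivalent
#' while avoiding instability when the fitted offset is near zero.
#'
#' @param trace a [photometry_trace()].
#' @param fit a [fit_bleach()] result for this trace; fitted automatically
#'   when `NULL`.
#' @return a `PhotometryTrace` holding the residual series.
#' @export
debleach <- function(trace, fit = NULL) {
  assert_that(inherits(trace, "PhotometryTrace"), "trace must be a PhotometryTrace")
  if (is.null(fit)) fit <- fit_bleach(trace)
  assert_that(inherits(fit, "BleachFit"), "fit must be a BleachFit")
  out <- trace
  out$F <- trace$F - predict_bleach(fit, trace$t)
  attr(out, "bleach_fit") <- fit
  out
}

#' Z-score a debleached trace against its baseline window
#'
#' Computes `z = (r - mu_b) / sigma_b` where `mu_b` and `sigma_b` are the
#' mean and standard deviation of the residual trace over the baseline
#' window. With `sd_source = "full"` the standard deviation is instead
#' taken over the whole trace (the mean stays baseline).
#'
#' @param trace residual `PhotometryTrace` from [debleach()].
#' @param baseline_window `c(t0, t1)` seconds; defaults to the window
#'   stored in the trace.
#' @param sd_source `"baseline"` (default) or `"full"`.
#' @return an object of class `ProcessedTrace`: list with `t`, `z`,
#'   `fs`, `baseline_window`, `mu_b`, `sd_b`, and `bleach_fit` provenance
#'   when present on the input.
#' @export
zscore_baseline <- function(trace, baseline_window = trace$baseline_window,
                            sd_source = c("baseline", "full")) {
  assert_that(inherits(trace, "PhotometryTrace"), "trace must be a PhotometryTrace")
  sd_source <- match.arg(sd_source)
  assert_that(!is.null(baseline_window) && length(baseline_window) == 2,
              "a baseline window (t0, t1) is required")
  sel <- trace$t >= baseline_window[1] & trace$t <= baseline_window[2]
  assert_that(sum(sel) >= 10, "baseline window must contain >= 10 samples")
  mu_b <- mean(trace$F[sel])
  sd_b <- if (sd_source == "baseline") sd(trace$F[sel]) else sd(trace$F)
  if (!(sd_b > 0)) abort("zero variance in the baseline window")
  structure(list(t = trace$t, z = (trace$F - mu_b) / sd_b, fs = trace$fs,
                 baseline_window = baseline_window, mu_b = mu_b, sd_b = sd_b,
                 bleach_fit = attr(trace, "bleach_fit")),
            class = "ProcessedTrace")
}

#' LOESS smoothing of a time series
#'
#' Locally weighted linear regression with tricube weights: each output
#' point is the prediction of a weighted linear fit over the `frac * n`
#' nearest samples. With `frac = 1` every local fit uses all points
#' (weighted by tricube distance from the evaluation point). No
#' robustness iterations are applied.
#'
#' @param x sample times (or a `ProcessedTrace`, in which case `y` is
#'   ignored and the smoothed series is stored as `z_smooth`).
#' @param y values to smooth.
#' @param frac smoothing fraction in (0, 1\] (default 0.1).
#' @return smoothed numeric vector aligned with `x`, or the
#'   `ProcessedTrace` with `z_smooth` added.
#' @export
loess_smooth <- function(x, y = NULL, frac = 0.1) {
  assert_that(is_number(frac) && frac > 0 && frac <= 1,
              "frac must lie in (0, 1]")
  if (inherits(x, "ProcessedTrace")) {
    x$z_smooth <- loess_smooth(x$t, x$z, frac = frac)
    return(x)
  }
  assert_that(length(x) == length(y), "x and y lengths differ")
  assert_that(length(x) >= 10, "need >= 10 points to smooth")
  assert_that(floor(frac * length(x)) >= 2,
              "frac too small: local window has < 2 points")
  sm <- lowess(x, y, f = frac, iter = 0, delta = 0)
  # lowess sorts by x; map back to input order (x is strictly increasing
  # for traces, but keep this general)
  sm$y[match(x, sm$x)]
}

#' Trapezoidal area under the z-scored signal
#'
#' Integrates the z-score series over a time window with the trapezoidal
#' rule, in z-score-seconds. Window endpoints are snapped to the nearest
#' sample times; both snapped endpoints are included, so the integral is
#' additive over adjacent windows sharing a boundary sample.
#'
#' @param processed a `ProcessedTrace` (or any list with `t` and `z`).
#' @param window `c(start, end)` seconds, within the trace span.
#' @param use_smoothed integrate `z_smooth` instead of `z` when available.
#' @return an object of class `AUCResult`: list with `window` (snapped),
#'   `auc`.
#' @export
auc_window <- function(processed, window, use_smoothed = FALSE) {
  t <- processed$t
  z <- if (use_smoothed && !is.null(processed$z_smooth)) processed$z_smooth
       else processed$z
  assert_that(length(window) == 2 && window[1] < window[2],
              "window must be (start, end) with start < end")
  assert_that(window[1] >= t[1] - 1e-9 && window[2] <= t[length(t)] + 1e-9,
              "window must lie within the trace span")
  i0 <- which.min(abs(t - window[1]))
  i1 <- which.min(abs(t - window[2]))
  if (i1 <= i0) abort("window snaps to fewer than 2 samples")
  idx <- i0:i1
  auc <- sum(diff(t[idx]) * (head(z[idx], -1) + tail(z[idx], -1)) / 2)
  structure(list(window = c(t[i0], t[i1]), auc = auc), class = "AUCResult")
}

#' Full photometry processing session
#'
#' Composes the pipeline: bleach fit, debleach, baseline z-score, LOESS
#' smoothing, and a trapezoidal AUC per analysis window (e.g. pre /
#' during / post stimulation). AUCs are computed on the unsmoothed
#' z-score by default; the LOESS curve serves visualization.
#'
#' @param trace a [photometry_trace()] with a baseline window (or one
#'   supplied via `baseline_window`).
#' @param windows named list of `c(start, end)` windows (seconds).
#' @param baseline_window overrides the trace's baseline window.
#' @param frac LOESS smoothing fraction (default 0.1).
#' @param model bleach model: `"auto"`, `"mono"` or `"bi"`.
#' @param sd_source passed to [zscore_baseline()].
#' @param auc_on `"z"` (default) or `"z_smooth"`.
#' @return list with `processed` (a `ProcessedTrace` incl. `z_smooth`),
#'   `fit` (the `BleachFit`), and `auc` (data.frame: window name, snapped
#'   start/end, auc).
#' @export
process_session <- function(trace, windows = list(),
                            baseline_window = trace$baseline_window,
                            frac = 0.1, model = "auto",
                            sd_source = "baseline", auc_on = c("z", "z_smooth")) {
  auc_on <- match.arg(auc_on)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("process_session failed at stage '", name, "': ",
            conditionMessage(e))
    })
  }
  fit <- stage("fit_bleach", fit_bleach(trace, model = model))
  res <- stage("debleach", debleach(trace, fit))
  proc <- stage("zscore_baseline",
                zscore_baseline(res, baseline_window, sd_source = sd_source))
  proc <- stage("loess_smooth", loess_smooth(proc, frac = frac))
  auc_tab <- NULL
  if (length(windows) > 0) {
    rows <- lapply(seq_along(windows), function(i) {
      a <- stage(paste0("auc[", names(windows)[i], "]"),
                 auc_window(proc, windows[[i]],
                            use_smoothed = auc_on == "z_smooth"))
      data.frame(window = names(windows)[i], start = a$window[1],
                 end = a$window[2], auc = a$auc, stringsAsFactors = FALSE)
    })
    auc_tab <- do.call(rbind, rows)
  }
  list(processed = proc, fit = fit, auc = auc_tab)
}
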