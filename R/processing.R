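# Respirogram processing: smoothing, event segmentation, dynamic oxygen
# uptake rate (R_S) extraction and oxygen consumption (OC) per addition.

#' Smooth the DO signal of a trace
#'
#' Noise suppression before numerical differentiation. Moving average uses a
#' centered window that shrinks symmetrically at the ends; the polynomial
#' filter is Savitzky-Golay (order 2).
#'
#' @param trace A [respirogram_trace()].
#' @param window Odd window length in samples, >= 3 and < trace length.
#' @param method `"moving-average"` or `"polynomial-filter"`.
#' @return A trace on the same time grid with smoothed `do_signal`.
#' @export
smooth_trace <- function(trace, window = 5,
                         method = c("moving-average", "polynomial-filter")) {
  stopifnot(inherits(trace, "respirogram_trace"))
  method <- match.arg(method)
  n <- length(trace$do_signal)
  if (window %% 2 != 1 || window < 3 || window >= n)
    stop("`window` must be odd, >= 3 and smaller than the trace length",
         call. = FALSE)
  y <- trace$do_signal
  if (method == "moving-average") {
    sm <- as.numeric(stats::filter(y, rep(1 / window, window), sides = 2))
    h <- (window - 1L) %/% 2L
    for (i in seq_len(h)) {          # shrink window at the edges
      sm[i] <- mean(y[1:(2 * i - 1)])
      sm[n - i + 1L] <- mean(y[(n - 2 * i + 2):n])
    }
  } else {
    sm <- signal::sgolayfilt(y, p = 2, n = window)
  }
  out <- trace
  # probe-noise allowance can be shaved by the smoother; keep within bounds
  out$do_signal <- pmin(pmax(sm, 0), trace$do_sat * 1.05)
  out
}

rolling_all <- function(x, w) {
  # TRUE at i when x[i..i+w-1] are all TRUE (right-aligned lookahead)
  n <- length(x)
  if (w <= 1) return(x)
  cs <- cumsum(c(x, rep(FALSE, w)))
  ok <- (cs[(w + 1):(n + w)] - cs[1:n]) == w
  ok[(n - w + 2):n] <- FALSE
  ok
}

#' Segment a respirogram into addition events
#'
#' Each substrate pulse drives DO down to a minimum followed by a recovery to
#' a stable value once the substrate is exhausted. A segment runs from the
#' addition instant to the first time after the DO minimum at which DO stays
#' within `epsilon` of the pre-addition baseline for `stability_window`
#' consecutive samples.
#'
#' @param trace A [respirogram_trace()].
#' @param addition_times Explicit addition instants (hours). When `NULL`,
#'   additions are detected as drops of at least `delta` below the running
#'   baseline.
#' @param delta Detection threshold: DO drop below baseline flagging an
#'   addition, mg O2 L-1.
#' @param epsilon Stability tolerance around the baseline, mg O2 L-1.
#' @param stability_window Number of consecutive in-tolerance samples
#'   declaring recovery.
#' @param baseline_window Samples averaged before the addition for the
#'   baseline.
#' @param baseline_gap Samples skipped immediately before the addition when
#'   averaging the baseline. On a smoothed trace the samples within half a
#'   smoothing window of the pulse already feel the post-pulse drop; skip
#'   them.
#' @return A data.frame with one row per event: `event_index`, `t_start`,
#'   `t_end`, `baseline_do`.
#' @export
segment_events <- function(trace, addition_times = NULL, delta = 0.3,
                           epsilon = 0.05, stability_window = 6,
                           baseline_window = 6, baseline_gap = 0) {
  stopifnot(inherits(trace, "respirogram_trace"))
  tt <- trace$time
  y <- trace$do_signal
  n <- length(tt)

  if (is.null(addition_times) && !is.null(trace$additions))
    addition_times <- trace$additions

  if (is.null(addition_times)) {
    # detection mode: walk the trace, track a stable baseline, flag drops
    addition_idx <- integer(0)
    i <- baseline_window + 1L
    while (i <= n) {
      base <- mean(y[max(1, i - baseline_window):(i - 1)])
      if (y[i] < base - delta) {
        # back up to the last sample still within epsilon of the baseline
        j <- i
        while (j > 1 && y[j - 1] < base - epsilon) j <- j - 1L
        addition_idx <- c(addition_idx, j)
        # skip past the excursion: next index where DO is back near baseline
        k <- i
        stable <- abs(y - base) < epsilon
        k <- k + 1L
        while (k <= n && !all(stable[k:min(n, k + stability_window - 1)])) k <- k + 1L
        i <- k + stability_window
      } else i <- i + 1L
    }
    if (!length(addition_idx))
      return(data.frame(event_index = integer(0), t_start = numeric(0),
                        t_end = numeric(0), baseline_do = numeric(0)))
    addition_times <- tt[addition_idx]
  }

  addition_times <- sort(addition_times)
  out <- lapply(seq_along(addition_times), function(e) {
    i0 <- which.min(abs(tt - addition_times[e]))
    pre <- max(1, i0 - baseline_gap - baseline_window):
      max(1, i0 - baseline_gap - 1)
    baseline <- mean(y[pre])
    limit <- if (e < length(addition_times))
      max(which(tt < addition_times[e + 1])) else n
    seg <- i0:limit
    imin <- seg[which.min(y[seg])]
    after <- seg[seg >= imin]
    near <- abs(y[after] - baseline) < epsilon
    ok <- rolling_all(near, min(stability_window, length(near)))
    hit <- which(ok)
    if (!length(hit))
      stop(sprintf("event %d never restabilizes at its baseline before %s",
                   e, if (limit == n) "the trace ends" else "the next addition"),
           call. = FALSE)
    i_end <- after[hit[1] + min(stability_window, length(near)) - 1L]
    data.frame(event_index = e, t_start = tt[i0], t_end = tt[i_end],
               baseline_do = baseline)
  })
  do.call(rbind, out)
}

#' Dynamic oxygen uptake rate over one event
#'
#' Derivative mode implements R_S as the (sign-flipped, floored) time
#' derivative of DO. Mass-balance mode corrects for reaeration,
#' `R_S = kla * (baseline - DO) - dDO/dt`, which makes the integral of R_S a
#' true exogenous oxygen consumption relative to the pre-addition steady
#' state. Derivatives are centered finite differences on the smoothed signal
#' with one-sided stencils at the ends.
#'
#' @param trace A (smoothed) [respirogram_trace()].
#' @param t_start,t_end Event bounds, hours.
#' @param baseline_do Pre-addition baseline DO, mg O2 L-1.
#' @param constants A [reactor_constants()]; mass-balance mode requires a
#'   finite `kla`.
#' @param mode `"mass-balance"` (default) or `"derivative"`.
#' @return A data.frame `time`, `rs` (mg O2 L-1 h-1, floored at 0).
#' @export
compute_rs <- function(trace, t_start, t_end, baseline_do, constants,
                       mode = c("mass-balance", "derivative")) {
  stopifnot(inherits(trace, "respirogram_trace"))
  mode <- match.arg(mode)
  sel <- trace$time >= t_start & trace$time <= t_end
  tt <- trace$time[sel]
  y <- trace$do_signal[sel]
  if (length(tt) < 3)
    stop("event segment must contain at least 3 samples", call. = FALSE)
  ddo <- finite_diff(tt, y)
  if (mode == "derivative") {
    rs <- pmax(0, -ddo)
  } else {
    kla <- constants$kla
    if (is.null(kla) || is.na(kla))
      stop("mass-balance mode requires `kla` (supply it or use estimate_kla)",
           call. = FALSE)
    rs <- pmax(0, kla * (baseline_do - y) - ddo)
  }
  data.frame(time = tt, rs = rs)
}

finite_diff <- function(t, y) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  d
}

#' Oxygen consumption of one event
#'
#' Trapezoidal integral of the dynamic oxygen uptake rate over the event.
#'
#' @param rs_series A data.frame `time`, `rs` as returned by [compute_rs()].
#' @return OC, mg O2 L-1 (nonnegative).
#' @export
compute_oc <- function(rs_series) {
  if (nrow(rs_series) < 2)
    stop("cannot integrate a series with fewer than 2 samples", call. = FALSE)
  if (any(diff(rs_series$time) <= 0))
    stop("rs_series times must be increasing", call. = FALSE)
  max(0, pracma::trapz(rs_series$time, rs_series$rs))
}

#' Estimate the oxygen transfer coefficient from a recovery tail
#'
#' After substrate exhaustion, DO relaxes exponentially back to the baseline
#' at rate kla: `DO(t) = baseline - (baseline - DO0) * exp(-kla * (t - t0))`.
#' A log-linear regression on `baseline - DO` seeds a nonlinear least-squares
#' refinement.
#'
#' @param time,do Recovery-tail samples (hours, mg O2 L-1), DO rising toward
#'   `baseline`.
#' @param baseline Stable DO the tail relaxes to, mg O2 L-1.
#' @return A list `kla` (h-1), `do0`, `rss` (residual sum of squares).
#' @export
estimate_kla <- function(time, do, baseline) {
  keep <- (baseline - do) > 1e-3
  if (sum(keep) < 3 || baseline - do[1] < 0.05)
    stop("segment shows no DO deficit to fit a reaeration curve to",
         call. = FALSE)
  t0 <- time[1]
  lf <- stats::lm(log(baseline - do[keep]) ~ I(time[keep] - t0))
  kla0 <- -stats::coef(lf)[[2]]
  if (!is.finite(kla0) || kla0 <= 0)
    stop("DO is not recovering toward the baseline; cannot estimate kla",
         call. = FALSE)
  d0 <- baseline - exp(stats::coef(lf)[[1]])
  df <- data.frame(t = time - t0, y = do)
  fit <- try(minpack.lm::nlsLM(
    y ~ baseline - (baseline - d0) * exp(-kla * t), data = df,
    start = list(kla = kla0, d0 = d0),
    lower = c(1e-6, -Inf), upper = c(1e4, baseline),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(kla = kla0, do0 = d0, rss = sum(stats::resid(lf)^2)))
  cf <- stats::coef(fit)
  list(kla = cf[["kla"]], do0 = cf[["d0"]], rss = sum(stats::resid(fit)^2))
}

#' Process a trace into addition events
#'
#' Runs smoothing, segmentation, R_S extraction and OC integration, and
#' attaches the design bookkeeping (in-reactor substrate S per pulse and,
#' when available, pre-addition biomass X_T). In derivative mode the OC
#' integral is terminated at the DO minimum (beyond it the raw derivative is
#' dominated by reaeration, not uptake).
#'
#' @param trace A [respirogram_trace()].
#' @param schedule An [addition_schedule()] aligned with the trace's events.
#' @param constants A [reactor_constants()]. `kla = NA` in mass-balance mode
#'   triggers estimation from the first event's recovery tail.
#' @param mode `"mass-balance"` or `"derivative"` (see [compute_rs()]).
#' @param x_t Optional biomass per event, mg TSS L-1, overriding the
#'   schedule's OD readings.
#' @param cal A [calibration_curve()] for OD-based biomass.
#' @param smooth_window,smooth_method Passed to [smooth_trace()]. The
#'   defaults (Savitzky-Golay, 21 samples) suit probe noise of a few
#'   hundredths of a mg O2 L-1 at second-scale sampling; shrink the window
#'   for sparsely sampled traces.
#' @param peak_window `rs_peak` is read off the R_S series after a centered
#'   moving average of this many samples, so the peak statistic is not the
#'   maximum of raw differentiation noise. Use 1 for the raw maximum.
#' @param ... Passed to [segment_events()].
#' @return A list of `addition_event` objects, each with fields
#'   `event_index`, `t_start`, `t_end`, `baseline_do`, `s_added`, `x_t`,
#'   `rs_series`, `oc`, `rs_peak`; the list carries the kla used as
#'   attribute `"kla"`.
#' @export
process_trace <- function(trace, schedule, constants = reactor_constants(),
                          mode = c("mass-balance", "derivative"),
                          x_t = NULL, cal = calibration_curve(),
                          smooth_window = 21,
                          smooth_method = "polynomial-filter",
                          peak_window = 11, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "addition_schedule"))
  sm <- smooth_trace(trace, window = smooth_window, method = smooth_method)
  segs <- segment_events(sm, baseline_gap = smooth_window %/% 2, ...)
  if (!nrow(segs)) stop("no addition events found in trace", call. = FALSE)
  n_ev <- nrow(segs)
  if (n_ev > length(schedule$dilution_fractions))
    stop("more events detected than pulses in the schedule", call. = FALSE)

  if (mode == "mass-balance" && (is.null(constants$kla) || is.na(constants$kla))) {
    # estimate kla from the first event's recovery tail
    sel <- sm$time >= segs$t_start[1] & sm$time <= segs$t_end[1]
    tt <- sm$time[sel]; y <- sm$do_signal[sel]
    imin <- which.min(y)
    est <- estimate_kla(tt[imin:length(tt)], y[imin:length(y)],
                        segs$baseline_do[1])
    constants$kla <- est$kla
  }

  if (is.null(x_t)) {
    x_t <- if (!is.null(schedule$biomass_od_per_event))
      od_to_biomass(schedule$biomass_od_per_event, cal)
    else rep(NA_real_, n_ev)
  }

  events <- lapply(seq_len(n_ev), function(e) {
    rs <- compute_rs(sm, segs$t_start[e], segs$t_end[e], segs$baseline_do[e],
                     constants, mode = mode)
    rs_oc <- rs
    if (mode == "derivative") {
      sel <- sm$time >= segs$t_start[e] & sm$time <= segs$t_end[e]
      imin <- which.min(sm$do_signal[sel])
      rs_oc <- rs[seq_len(max(2, imin)), ]
    }
    structure(
      list(event_index = e, t_start = segs$t_start[e], t_end = segs$t_end[e],
           baseline_do = segs$baseline_do[e],
           s_added = in_reactor_substrate(schedule, e),
           x_t = x_t[e], rs_series = rs, oc = compute_oc(rs_oc),
           rs_peak = peak_rs(rs$rs, peak_window)),
      class = "addition_event")
  })
  attr(events, "kla") <- constants$kla
  attr(events, "mode") <- mode
  events
}

peak_rs <- function(rs, window) {
  if (window <= 1 || window >= length(rs)) return(max(rs))
  max(stats::filter(rs, rep(1 / window, window), sides = 2), na.rm = TRUE)
}

#' @export
print.addition_event <- function(x, ...) {
  cat(sprintf(
    "<addition_event %d> [%.3f, %.3f] h  S=%.3f  X_T=%.1f  OC=%.3f  Rs_peak=%.2f\n",
    x$event_index, x$t_start, x$t_end, x$s_added, x$x_t, x$oc, x$rs_peak))
  invisible(x)
}
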