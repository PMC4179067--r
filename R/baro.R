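# Barometric altitude and conditioning. Pressure is converted to altitude
# with the international barometric formula, detrended by the rest-period
# baseline, then conditioned by a causal 4-point moving average (Method A)
# optionally cascaded with a first-order whitening filter (Method B) that
# removes the short-term serial correlation of environmental pressure
# fluctuations.

#' Standard sea-level pressure, Pa
#' @export
P0_SEA_LEVEL <- 101325

#' Pressure to altitude (barometric formula)
#'
#' `h = 44300 * (1 - (p / p0)^0.19)` with `p0 = 1013.25 hPa`; monotone
#' decreasing in pressure. Relative altitude changes are valid even when
#' local pressure differs from the standard atmosphere.
#'
#' @param p pressure, Pa (vectorized, must be > 0).
#' @return altitude above the standard sea level, m.
#' @export
pressure_to_altitude <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("pressure_to_altitude: pressure must be positive and finite")
  }
  44300 * (1 - (p / P0_SEA_LEVEL)^0.19)
}

#' Altitude to pressure (inverse barometric formula)
#' @param h altitude, m (must be below 44300).
#' @return pressure, Pa.
#' @export
altitude_to_pressure <- function(h) {
  if (any(h >= 44300)) stop("altitude_to_pressure: altitude out of range")
  P0_SEA_LEVEL * (1 - h / 44300)^(1 / 0.19)
}

#' Design the first-order barometric-noise whitening filter
#'
#' Discrete filter `H(z) = g0 * (z - b) / (z - a)` with the pole placed at
#' `pole_hz` (`a = exp(-2*pi*pole_hz/fs)`) and the zero and gain solved
#' exactly from two constraints: DC gain `|H(1)| = dc_gain` and unity gain
#' at the Nyquist frequency `|H(-1)| = 1`. With the defaults (50 Hz, pole
#' 1 Hz, DC gain 0.21, unity at 25 Hz) the implied zero lands near 0.21 Hz,
#' about two octaves below the pole.
#'
#' @param fs sampling rate, Hz.
#' @param pole_hz pole frequency, Hz.
#' @param dc_gain DC gain (dimensionless).
#' @param unity_hz frequency of the unity-gain constraint; must equal the
#'   Nyquist frequency `fs/2`, where the constraint is enforced at `z = -1`.
#' @return object of class `whitening_filter` with coefficients `a`, `b`,
#'   `g0` and the implied `zero_hz`.
#' @export
design_whitening_filter <- function(fs = 50, pole_hz = 1, dc_gain = 0.21,
                                    unity_hz = fs / 2) {
  if (!(pole_hz > 0 && pole_hz < unity_hz && unity_hz <= fs / 2)) {
    stop("design_whitening_filter: need 0 < pole_hz < unity_hz <= fs/2")
  }
  if (abs(unity_hz - fs / 2) > 1e-9) {
    stop("design_whitening_filter: the unity-gain constraint is enforced at the Nyquist frequency (unity_hz = fs/2)")
  }
  a <- exp(-2 * pi * pole_hz / fs)
  c1 <- dc_gain * (1 - a)   # g0 * (1 - b)
  c2 <- 1 + a               # g0 * (1 + b)
  g0 <- (c1 + c2) / 2
  b <- (c2 - c1) / (c2 + c1)
  if (abs(b) >= 1) stop("design_whitening_filter: infeasible constraints (zero outside the unit circle)")
  structure(list(fs = fs, pole_hz = pole_hz, dc_gain = dc_gain,
                 unity_hz = unity_hz, a = a, b = b, g0 = g0,
                 zero_hz = -log(b) * fs / (2 * pi)),
            class = "whitening_filter")
}

#' Frequency response of a whitening filter
#' @param wf `whitening_filter` object.
#' @param f frequency, Hz (vectorized).
#' @return complex response `H(exp(2i*pi*f/fs))`.
#' @export
whitening_response <- function(wf, f) {
  z <- exp(2i * pi * f / wf$fs)
  wf$g0 * (z - wf$b) / (z - wf$a)
}

#' Apply a whitening filter to a signal (causal, streaming)
#'
#' Difference equation `y_k = a*y_{k-1} + g0*(x_k - b*x_{k-1})`. State can
#' be carried across calls so a log may be processed in chunks with output
#' identical to one-shot processing.
#'
#' @param wf `whitening_filter` object.
#' @param x input series.
#' @param state filter state from a previous call, or NULL for zero initial
#'   conditions.
#' @return list with `y` (filtered series) and `state`.
#' @export
whitening_apply <- function(wf, x, state = NULL) {
  if (is.null(state)) state <- list(x_prev = 0, y_prev = 0)
  n <- length(x)
  if (n == 0L) return(list(y = numeric(0), state = state))
  u <- wf$g0 * (x - wf$b * c(state$x_prev, x[-n]))
  y <- as.numeric(stats::filter(u, wf$a, method = "recursive",
                                init = state$y_prev))
  list(y = y, state = list(x_prev = x[n], y_prev = y[n]))
}

#' Apply a causal M-point moving average (streaming)
#'
#' `y_k = mean(x_{k-M+1}, ..., x_k)` with zero initial conditions; the
#' group delay is `(M-1)/2` samples. State can be carried across calls.
#'
#' @param x input series.
#' @param M filter length (default 4).
#' @param state buffer of the last `M-1` inputs from a previous call.
#' @return list with `y` and `state`.
#' @export
moving_average_apply <- function(x, M = 4L, state = NULL) {
  M <- as.integer(M)
  if (is.null(state)) state <- rep(0, M - 1L)
  n <- length(x)
  if (n == 0L) return(list(y = numeric(0), state = state))
  xx <- c(state, x)
  y <- as.numeric(stats::filter(xx, rep(1 / M, M), sides = 1))[M:(M + n - 1L)]
  list(y = y, state = xx[(length(xx) - M + 2L):length(xx)])
}

#' Streaming pressure-altitude conditioner
#'
#' Builds the conditioning chain of the selected method: pressure to
#' altitude, baseline subtraction (rest-period bias capture), causal
#' 4-point moving average, and for Method B the whitening filter cascaded
#' after the moving average. The returned object's `$process(p)` function
#' is causal and carries filter state across calls.
#'
#' @param rest rest statistics from [capture_rest()] (baro baseline).
#' @param cfg [fusion_config()]; `method` selects the chain.
#' @return object of class `baro_conditioner` with elements `process`
#'   (function of a pressure vector returning conditioned altitude),
#'   `method` and `filter` (the whitening filter, or NULL for Method A).
#' @export
baro_conditioner <- function(rest, cfg = fusion_config()) {
  if (!cfg$method %in% c("A", "B")) stop("unknown conditioning method: ", cfg$method)
  wf <- if (cfg$method == "B") design_whitening_filter(fs = 1 / cfg$Ts) else NULL
  ma_state <- NULL
  wh_state <- NULL
  process <- function(p) {
    x <- pressure_to_altitude(p) - rest$baro_baseline
    r <- moving_average_apply(x, 4L, ma_state)
    ma_state <<- r$state
    y <- r$y
    if (!is.null(wf)) {
      r2 <- whitening_apply(wf, y, wh_state)
      wh_state <<- r2$state
      y <- r2$y
    }
    y
  }
  structure(list(process = process, method = cfg$method, filter = wf),
            class = "baro_conditioner")
}

#' Condition a pressure series in one call
#'
#' Convenience wrapper around [baro_conditioner()] for whole-log
#' processing.
#'
#' @param p pressure series, Pa.
#' @inheritParams baro_conditioner
#' @return conditioned relative pressure altitude, m.
#' @export
condition_pressure <- function(p, rest, cfg = fusion_config()) {
  baro_conditioner(rest, cfg)$process(p)
}

#' Plain-text report of the whitening-filter coefficients
#' @param wf `whitening_filter` object.
#' @return character vector, one line per quantity.
#' @export
whitening_report <- function(wf) {
  c(sprintf("fs_hz      = %.10g", wf$fs),
    sprintf("pole_hz    = %.10g", wf$pole_hz),
    sprintf("dc_gain    = %.10g", wf$dc_gain),
    sprintf("unity_hz   = %.10g", wf$unity_hz),
    sprintf("a (pole)   = %.10g", wf$a),
    sprintf("b (zero)   = %.10g", wf$b),
    sprintf("g0 (gain)  = %.10g", wf$g0),
    sprintf("zero_hz    = %.10g", wf$zero_hz))
}

#' @export
print.whitening_filter <- function(x, ...) {
  cat("First-order whitening filter H(z) = g0 (z - b) / (z - a)\n")
  cat(paste0("  ", whitening_report(x)), sep = "\n")
  invisible(x)
}
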