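# Evaluation: analytic reference models, RMSE, trial results and the
# Method A vs Method B statistical comparison.

#' Root mean square error between two series
#'
#' `sqrt(mean((est - ref)^2))` over equally long series.
#'
#' @param est estimated series.
#' @param ref reference series.
#' @return scalar RMSE (same units as the inputs).
#' @export
rmse <- function(est, ref) {
  if (length(est) != length(ref)) stop("rmse: series lengths differ")
  if (length(est) < 1L) stop("rmse: empty series")
  sqrt(mean((est - ref)^2))
}

#' Advance a series by a fractional number of samples
#'
#' Returns the series evaluated at `t + d*Ts` by linear interpolation
#' (constant extrapolation at the ends). Used to compensate the tracking
#' pipeline's structural group delay before comparison with a reference:
#' the complementary-filter recursion consumes the previous sample's
#' inputs, delaying both outputs by one sample, which is the default used
#' by [evaluate_track()] (the 1.5-sample moving-average delay on the
#' barometric path is largely offset by the phase lead of the closed loop
#' and does not add a net delay).
#'
#' @param t time base, s.
#' @param x series sampled at `t`.
#' @param d advance, in samples (may be fractional).
#' @param Ts sampling interval, s.
#' @return advanced series on the same time base.
#' @export
align_series <- function(t, x, d, Ts) {
  if (d == 0) return(x)
  stats::approx(t, x, xout = t + d * Ts, rule = 2)$y
}

#' Ballistic-fall evaluation window and analytic reference
#'
#' `T_start` is the first downward crossing of the specific-force norm
#' through `g/2` (entry into free fall); `T_end = T_start + sqrt(2*H/g)`
#' is the predicted first impact. The analytic reference over the window
#' is `v(t) = g*t`, `h(t) = g*t^2/2` (downward displacement and speed,
#' positive down, clocks starting at `T_start`).
#'
#' @param log sensor log of a free-fall trial.
#' @param H drop height, m.
#' @param g gravity, m/s^2.
#' @return list with `T_start`, `T_end`, `index` (samples inside the
#'   window) and `reference` (data.frame t, h_ref, v_ref).
#' @export
free_fall_window <- function(log, H, g = 9.81) {
  log <- as_imu_log(as.data.frame(log))
  fn <- sqrt(log$ax^2 + log$ay^2 + log$az^2)
  below <- fn < g / 2
  cross <- which(!below[-length(below)] & below[-1]) + 1L
  if (below[1]) cross <- c(1L, cross)
  if (!length(cross)) stop("free_fall_window: no g/2 crossing found (no ballistic phase?)")
  T_start <- log$t[cross[1]]
  T_end <- T_start + sqrt(2 * H / g)
  idx <- which(log$t >= T_start & log$t <= T_end)
  s <- log$t[idx] - T_start
  list(T_start = T_start, T_end = T_end, index = idx,
       reference = data.frame(t = log$t[idx], h_ref = g * s^2 / 2,
                              v_ref = g * s))
}

#' Reference height and velocity from an encoder angle series
#'
#' `h_k = L * sin(theta_k)`; velocity by central finite difference
#' `(h_{k+1} - h_{k-1}) / (2*Ts)` with one-sided differences at the ends.
#'
#' @param theta angle series, rad, uniformly sampled.
#' @param L lever arm, m.
#' @param Ts sampling interval, s.
#' @return data.frame with `height` and `velocity`.
#' @export
circular_reference <- function(theta, L, Ts) {
  h <- L * sin(theta)
  n <- length(h)
  v <- numeric(n)
  if (n >= 3L) v[2:(n - 1L)] <- (h[3:n] - h[1:(n - 2L)]) / (2 * Ts)
  if (n >= 2L) {
    v[1] <- (h[2] - h[1]) / Ts
    v[n] <- (h[n] - h[n - 1L]) / Ts
  }
  data.frame(height = h, velocity = v)
}

trial_result <- function(scenario, method, height_rmse, velocity_rmse,
                         velocity_bias, n) {
  data.frame(scenario = scenario, method = method,
             height_rmse = height_rmse, velocity_rmse = velocity_rmse,
             velocity_bias = velocity_bias, n_samples = n)
}

#' Evaluate a vertical track against its simulated scenario
#'
#' Computes scenario-appropriate height and velocity RMSE against the
#' analytic reference: zero for no-motion; `L*sin(theta)` and its central
#' difference over the steady-rotation window for circular motion; the
#' ballistic model over the fall window (fall-relative displacement and
#' velocity) for free fall; the truth trajectory for the squat. Estimates
#' are advanced by the pipeline's structural group delay before
#' comparison (see [align_series()]).
#'
#' @param track `vertical_track` from [track_vertical()].
#' @param sim simulated scenario (list with `truth`, `log`) or a
#'   `scenario_truth`.
#' @param delay_height,delay_velocity group-delay compensation in samples.
#' @return one-row data.frame (`TrialResult`): scenario, method,
#'   height_rmse (m), velocity_rmse (m/s), velocity_bias (m/s), n_samples.
#' @export
evaluate_track <- function(track, sim, delay_height = 1, delay_velocity = 1) {
  truth <- if (inherits(sim, "scenario_truth")) sim else sim$truth
  est <- track$estimates
  Ts <- track$cfg$Ts
  if (nrow(est) != length(truth$t)) {
    stop("evaluate_track: estimate and truth lengths differ")
  }
  method <- track$cfg$method
  h_al <- align_series(est$t, est$height, delay_height, Ts)
  v_al <- align_series(est$t, est$velocity, delay_velocity, Ts)
  bias <- mean(est$velocity)

  if (truth$scenario == "no-motion") {
    return(trial_result("no-motion", method,
                        rmse(h_al, numeric(length(h_al))),
                        rmse(v_al, numeric(length(v_al))),
                        bias, length(h_al)))
  }
  if (truth$scenario == "circular") {
    i <- which(truth$t >= truth$params$t_steady)
    ref <- circular_reference(truth$theta[i], truth$params$L, Ts)
    return(trial_result("circular", method,
                        rmse(h_al[i], ref$height),
                        rmse(v_al[i], ref$velocity),
                        bias, length(i)))
  }
  if (truth$scenario == "free-fall") {
    fw <- free_fall_window(sim$log, H = truth$params$H, g = truth$g)
    i <- fw$index
    disp <- h_al[i[1]] - h_al[i]            # downward displacement since T_start
    speed <- -(v_al[i] - v_al[i[1]])        # downward speed since T_start
    return(trial_result("free-fall", method,
                        rmse(disp, fw$reference$h_ref),
                        rmse(speed, fw$reference$v_ref),
                        bias, length(i)))
  }
  if (truth$scenario == "squat") {
    return(trial_result("squat", method,
                        rmse(h_al, truth$height),
                        rmse(v_al, truth$velocity),
                        bias, length(h_al)))
  }
  stop("evaluate_track: unknown scenario: ", truth$scenario)
}

#' Compare conditioning methods over paired trials
#'
#' For each metric, applies the Bartlett test for equal variance and the
#' paired-sample Wilcoxon signed rank test (exact null distribution for
#' small N without ties) at the 5% significance level.
#'
#' @param results_A,results_B data.frames of paired trial results (same
#'   trials, Method A and Method B) with the metric columns.
#' @param metrics metric columns to compare.
#' @param level significance level.
#' @return data.frame: metric, mean_A, mean_B, bartlett_stat, bartlett_p,
#'   wilcoxon_V, wilcoxon_p, significant.
#' @export
compare_methods <- function(results_A, results_B,
                            metrics = c("height_rmse", "velocity_rmse"),
                            level = 0.05) {
  if (nrow(results_A) != nrow(results_B)) {
    stop("compare_methods: unpaired result lists")
  }
  if (nrow(results_A) < 5L) stop("compare_methods: need at least 5 paired trials")
  out <- lapply(metrics, function(m) {
    a <- results_A[[m]]; b <- results_B[[m]]
    bt <- stats::bartlett.test(list(A = a, B = b))
    if (all(a == b)) {
      # all paired differences zero: no evidence of any difference
      wV <- NA_real_; wp <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = TRUE))
      wV <- unname(wt$statistic); wp <- wt$p.value
    }
    data.frame(metric = m, mean_A = mean(a), mean_B = mean(b),
               bartlett_stat = unname(bt$statistic), bartlett_p = bt$p.value,
               wilcoxon_V = wV, wilcoxon_p = wp,
               significant = wp < level)
  })
  do.call(rbind, out)
}

#' Summarize trial results as mean and SD per scenario and method
#'
#' @param results data.frame of trial results (rows from
#'   [evaluate_track()]).
#' @return data.frame: scenario, method, n_trials, and mean/SD of each
#'   RMSE metric.
#' @export
summarize_results <- function(results) {
  key <- interaction(results$scenario, results$method, drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    data.frame(scenario = d$scenario[1], method = d$method[1],
               n_trials = nrow(d),
               height_rmse_mean = mean(d$height_rmse),
               height_rmse_sd = stats::sd(d$height_rmse),
               velocity_rmse_mean = mean(d$velocity_rmse),
               velocity_rmse_sd = stats::sd(d$velocity_rmse))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$scenario, out$method), ]
}
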