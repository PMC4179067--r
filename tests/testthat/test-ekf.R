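# Attitude EKF: bias model, process noise, measurement Jacobian, vector
# selection, convergence and covariance health.

test_that("bias transition handles the Gauss-Markov model and its limits", {
  # random-walk limit alpha = 0 with working defaults
  bt0 <- bias_transition(0, 0.02, 5e-4)
  expect_equal(bt0$phi, 1)
  expect_equal(diag(bt0$Qa), rep(0.02 * (5e-4)^2, 3))  # 5e-9
  # direct evaluation at alpha = 1, Ts = 0.02, sigma = 1
  bt1 <- bias_transition(1, 0.02, 1)
  expect_equal(diag(bt1$Qa), rep((1 - exp(-0.04)) / 2, 3), tolerance = 1e-12)
  expect_equal(bt1$phi, exp(-0.02))
  # strong mean reversion kills both transition and noise
  btInf <- bias_transition(500, 0.02, 1)
  expect_lt(btInf$phi, 1e-4)
  expect_lt(max(diag(btInf$Qa)), 1.1e-3)
  expect_error(bias_transition(-1, 0.02, 1), "alpha")
})

test_that("process noise has the trace-complement quaternion block", {
  sg <- pi / 180; Ts <- 0.02
  Q <- process_noise(quat_identity(), matrix(0, 4, 4), sg, Ts, diag(3) * 0)
  expect_equal(Q[1:4, 1:4], diag(c(1, 1, 1, 0)) * sg^2 * (Ts / 2)^2)
  expect_equal(process_noise(quat_identity(), matrix(0, 4, 4), 0, Ts,
                             diag(3))[1:4, 1:4], matrix(0, 4, 4))
  set.seed(9)
  for (i in 1:20) {
    q <- quat_normalize(rnorm(4))
    A <- matrix(rnorm(16, sd = 0.01), 4); Pq <- crossprod(A)
    Q <- process_noise(q, Pq, sg, Ts, diag(3) * 1e-9)
    expect_equal(Q, t(Q))
    expect_gte(min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  }
})

test_that("measurement Jacobian matches finite differences", {
  gn <- c(0, 0, 9.81)
  h_fun <- function(x) drop(oracle_Cbn(x[1:4]) %*% (-gn)) + x[5:7]
  set.seed(21)
  for (i in 1:20) {
    q <- quat_normalize(rnorm(4))
    x <- c(q, rnorm(3, sd = 0.05))
    H <- measurement_jacobian(q, gn)
    eps <- 1e-7
    H_fd <- matrix(0, 3, 7)
    for (j in 1:7) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + eps; xm[j] <- xm[j] - eps
      H_fd[, j] <- (h_fun(xp) - h_fun(xm)) / (2 * eps)
    }
    expect_equal(H, H_fd, tolerance = 1e-6)
  }
})

test_that("prediction is exact for zero rate and compounds rotations", {
  cfg <- fusion_config()
  cfg0 <- cfg_override(cfg, sigma_g = 0, sigma_ab = 0)
  state <- list(q = quat_identity(), b = c(0.01, 0, -0.01), P = diag(7) * 1e-4)
  out <- ekf_predict(state, c(0, 0, 0), cfg0)
  expect_equal(out$q, state$q)
  expect_equal(out$b, state$b)
  expect_equal(out$P, state$P, tolerance = 1e-12)
  # covariance trace never shrinks during prediction
  st <- list(q = quat_normalize(c(0.1, 0.2, 0, 1)), b = rep(0, 3),
             P = diag(7) * 1e-4)
  for (k in 1:20) {
    st2 <- ekf_predict(st, c(0.5, -0.2, 0.1), cfg)
    expect_gte(sum(diag(st2$P)), sum(diag(st$P)) - 1e-15)
    st <- st2
  }
  # 100 predicts at constant rate equal one closed-form rotation
  st <- list(q = quat_identity(), b = rep(0, 3), P = diag(7) * 1e-4)
  for (k in 1:100) st <- ekf_predict(st, c(pi / 5, 0, 0), cfg)
  expect_equal(st$q, quat_from_axis_angle(c(1, 0, 0), 100 * (pi / 5) * cfg$Ts),
               tolerance = 1e-9)
})

test_that("vector selection gates the leveling update per axis", {
  cfg <- fusion_config()
  state <- ekf_init(capture_rest(static_log(60), cfg), cfg)
  # level stationary: zero innovation, no state motion
  up <- ekf_update(state, c(0, 0, -9.81), cfg)
  expect_equal(up$diagnostics$innovation, c(0, 0, 0), tolerance = 1e-12)
  expect_true(up$diagnostics$updated)
  expect_equal(up$state$q, state$q, tolerance = 1e-12)
  expect_lte(sum(diag(up$state$P)), sum(diag(state$P)))
  # free fall: specific force zero, vertical-axis innovation |g| -> all
  # informative axes rejected, no update
  up_ff <- ekf_update(state, c(0, 0, 0), cfg)
  expect_false(up_ff$diagnostics$accepted[3])
  expect_false(up_ff$diagnostics$updated && any(abs(up_ff$state$q - state$q) > 1e-12))
  # mixed innovation (0.05g, 0.20g, 0.01g): only x and z pass the 150 mg gate
  g <- 9.81
  f <- c(0, 0, -g) + c(0.05 * g, 0.20 * g, 0.01 * g)
  up_mix <- ekf_update(state, f, cfg)
  expect_equal(unname(up_mix$diagnostics$accepted), c(TRUE, FALSE, TRUE))
})

test_that("free fall leaves attitude to gyro-only coasting", {
  # vector selection rejects an axis only when the predicted gravity
  # projection on it exceeds lambda_g; start from an attitude where
  # gravity projects well beyond the threshold on every axis, so the
  # ballistic (zero) specific force is rejected on all rows and the
  # quaternion equals pure gyro propagation, bitwise
  cfg <- fusion_config()
  q0 <- leveling_quaternion(-9.81 * c(1, 1, 1) / sqrt(3))
  set.seed(14)
  n <- 100
  omega <- matrix(rnorm(3 * n, sd = 0.3), n, 3)
  state <- list(q = q0, b = rep(0, 3), P = diag(7) * 1e-4)
  q_ref <- q0
  for (k in 1:n) {
    state <- ekf_predict(state, omega[k, ], cfg)
    up <- ekf_update(state, c(0, 0, 0), cfg)  # ballistic specific force
    state <- up$state
    q_ref <- quat_propagate(q_ref, omega[k, ], cfg$Ts)
    expect_false(up$diagnostics$updated)
  }
  expect_identical(state$q, q_ref)
})

test_that("a 5 degree initial tilt is leveled within 0.1 degree in 10 s", {
  cfg <- fusion_config()
  log <- static_log(500)  # 10 s, noise-free level data
  rest <- capture_rest(log, cfg)
  rest$initial_quaternion <- quat_from_axis_angle(c(1, 0, 0), 5 * pi / 180)
  out <- run_ekf(log, cfg, rest = rest)
  err <- inclination_error_deg(out$q[nrow(log), ], quat_identity())
  expect_lt(err, 0.1)
})

test_that("a constant vertical accelerometer bias is recovered", {
  # 20 mg on the vertical axis of a static sensor: estimate within 5 mg
  # of truth in at most 60 s (horizontal biases are unobservable from
  # leveling and trade off against tilt)
  cfg <- fusion_config()
  bias <- 20 * MG
  log <- static_log(3000, f_b = c(0, 0, -9.81 + bias))
  rest <- capture_rest(log, cfg)
  rest$initial_quaternion <- quat_identity()
  out <- run_ekf(log, cfg, rest = rest)
  expect_lt(abs(out$b[3000, 3] - bias), 5 * MG)
})

test_that("quaternion norm and covariance stay healthy under noise", {
  sim <- simulate_no_motion(duration = 20, errors = sensor_errors(seed = 4))
  cfg <- fusion_config()
  out <- run_ekf(sim$log, cfg)
  n <- nrow(sim$log)
  norms <- sqrt(rowSums(out$q^2))
  expect_lt(max(abs(norms - 1)), 1e-9)
  for (k in seq(10, n, by = 100)) {
    P <- out$P[[k]]
    expect_lt(max(abs(P - t(P))), 1e-10)
    expect_gte(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})
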