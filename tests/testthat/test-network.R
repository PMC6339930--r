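# Head-direction SOM ---------------------------------------------------------

test_that("trained SOM weights are unit vectors covering all directions", {
  hd <- train_hd_som(c(8, 8), n_samples = 10000, seed = 1)
  norms <- sqrt(colSums(hd$W^2))
  expect_equal(norms, rep(1, 64), tolerance = 1e-9)

  # the 2-D sheet folds onto the direction circle, so gaps larger than
  # the mean spacing occur at fold lines; coverage means no gap beyond
  # a small multiple of the mean spacing
  ang <- sort(hd$preferred)
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_lt(max(gaps), 4 * (2 * pi / 64))

  expect_error(train_hd_som(c(8, 8), epochs = 0),
               class = "gridscape_error_invalid_training")
  expect_error(train_hd_som(c(1, 2)), class = "gridscape_error_invalid_training")
})

test_that("hd_response is the cosine of the heading-preference difference", {
  hd <- train_hd_som(c(6, 6), n_samples = 4000, seed = 2)
  for (heading in c(0.3, 2.1, 5.5)) {
    r <- hd_response(hd, heading)
    expect_equal(r, cos(heading - hd$preferred), tolerance = 1e-9)
    expect_equal(which.max(r),
                 which.min(abs(atan2(sin(heading - hd$preferred),
                                     cos(heading - hd$preferred)))))
  }
  # aligned heading gives activation 1
  k <- 5
  expect_equal(hd_response(hd, hd$preferred[k])[k], 1, tolerance = 1e-9)
})

# Oscillators -----------------------------------------------------------------

test_that("unforced oscillators relax to the limit cycle of radius sqrt(mu)", {
  st <- list(u = c(0.2, 3), v = c(0, 0))
  p <- osc_params()
  for (i in seq_len(1000)) st <- step_oscillators(st, c(0, 0), 0, 0.01, p)
  expect_equal(sqrt(st$u^2 + st$v^2), c(1, 1), tolerance = 1e-3)
})

test_that("oscillator phase integrates the directional displacement", {
  p <- osc_params()
  # constant speed and hd activation over T steps
  s <- 0.4; hd_act <- 0.7; dt <- 0.01; n <- 500
  st <- list(u = 1, v = 0)
  phases <- numeric(n)
  for (i in seq_len(n)) {
    st <- step_oscillators(st, hd_act, s, dt, p)
    phases[i] <- atan2(st$v, st$u)
  }
  unwrapped <- cumsum(c(phases[1], atan2(sin(diff(phases)), cos(diff(phases)))))
  analytic <- (p$omega + p$beta * s * hd_act) * dt * seq_len(n)
  expect_lt(max(abs(unwrapped - analytic)) / max(analytic), 0.02)
  # the movement-driven extra phase alone
  extra <- unwrapped[n] - p$omega * dt * n
  expect_equal(extra, p$beta * s * hd_act * dt * n, tolerance = 1e-6)
})

test_that("s = 0 advances phase by omega*dt and preserves the radius", {
  p <- osc_params()
  st <- step_oscillators(list(u = 1, v = 0), 0.5, 0, 0.01, p)
  expect_equal(atan2(st$v, st$u), p$omega * 0.01, tolerance = 1e-12)
  expect_equal(sqrt(st$u^2 + st$v^2), 1, tolerance = 1e-12)
})

test_that("R and C++ oscillator paths agree", {
  p <- osc_params()
  u <- runif(8, -1, 1); v <- runif(8, -1, 1); om <- runif(8, 30, 60)
  r_step <- step_oscillators(list(u = u, v = v), (om - p$omega) / (p$beta * 0.3),
                             0.3, 0.01, p)
  c_step <- gridscape:::cpp_osc_step(u, v, om, p$mu, 0.01)
  expect_equal(r_step$u, as.numeric(c_step$u), tolerance = 1e-12)
  expect_equal(r_step$v, as.numeric(c_step$v), tolerance = 1e-12)

  # whole-trajectory drive equals the stepwise R loop
  traj <- tiny_square_traj(2)
  hd <- train_hd_som(c(4, 4), n_samples = 2000, seed = 3)
  chi <- oscillator_drive(traj, hd, p)
  st <- list(u = rep(1, 16), v = rep(0, 16))
  s <- speed_series(traj)
  for (k in 2:nrow(traj)) {
    st <- step_oscillators(st, hd_response(hd, traj$theta[k]), s[k], 0.01, p)
  }
  expect_equal(as.numeric(chi[nrow(traj), 1:16]), st$u, tolerance = 1e-9)
  expect_equal(as.numeric(chi[nrow(traj), 17:32]), st$v, tolerance = 1e-9)
})

# LAHN ------------------------------------------------------------------------

test_that("lahn_response implements the one-step recurrence exactly", {
  set.seed(4)
  net <- lahn_init(3, 4, seed = 4)
  chi <- rnorm(4); xi_prev <- rnorm(3)
  # hand-rolled double loop over Eq terms
  oracle <- numeric(3)
  for (i in 1:3) {
    oracle[i] <- sum(net$q[i, ] * chi) + sum(net$w[i, ] * xi_prev)
  }
  expect_equal(lahn_response(net, chi, xi_prev), oracle, tolerance = 1e-12)

  net0 <- net; net0$w[] <- 0
  expect_equal(lahn_response(net0, chi), drop(net0$q %*% chi), tolerance = 1e-12)
  expect_equal(lahn_settled_response(net0, chi), drop(net0$q %*% chi),
               tolerance = 1e-12)
  expect_error(lahn_response(net, rnorm(5)), class = "gridscape_error_shape")
})

test_that("settled response solves the lateral fixed point", {
  net <- lahn_init(5, 7, seed = 5)
  chi <- rnorm(7)
  xi <- lahn_settled_response(net, chi)
  # fixed point: xi == q chi + w xi
  expect_equal(xi, drop(net$q %*% chi + net$w %*% xi), tolerance = 1e-10)
  # matches the C++ replay route
  rep1 <- lahn_replay(matrix(chi, 1), net$q, net$w)
  expect_equal(as.numeric(rep1), xi, tolerance = 1e-10)
})

test_that("plasticity obeys the Hebbian/anti-Hebbian update equations", {
  net <- lahn_init(4, 6, eta_f = 0.02, eta_l = 0.03, seed = 6)
  chi <- rnorm(6); xi <- rnorm(4); xi_prev <- rnorm(4)
  up <- lahn_update(net, chi, xi, xi_prev)
  expect_equal(up$q, net$q + 0.02 * (outer(xi, chi) - net$q * xi^2),
               tolerance = 1e-12)
  w_expect <- net$w - 0.03 * outer(xi, xi_prev)
  diag(w_expect) <- 0
  expect_equal(up$w, w_expect, tolerance = 1e-12)
  expect_true(all(diag(up$w) == 0))

  frozen <- lahn_init(4, 6, eta_f = 0, eta_l = 0, seed = 6)
  up0 <- lahn_update(frozen, chi, xi, xi_prev)
  expect_identical(up0$q, frozen$q)
  expect_identical(up0$w, frozen$w)
})

test_that("a single neuron converges to the first principal direction", {
  set.seed(7)
  # anisotropic 2-D stream with a known top eigenvector
  C <- matrix(c(2, 1.2, 1.2, 1), 2)
  X <- matrix(rnorm(8000 * 2), ncol = 2) %*% chol(C)
  net <- lahn_init(1, 2, seed = 7)
  fit <- lahn_train(net, X)
  # power-iteration oracle on the sample covariance
  S <- crossprod(X) / nrow(X)
  v <- c(1, 0)
  for (i in 1:200) { v <- S %*% v; v <- v / sqrt(sum(v^2)) }
  q <- fit$net$q[1, ] / sqrt(sum(fit$net$q[1, ]^2))
  expect_gt(abs(sum(q * v)), 0.99)
})

test_that("the LAHN recovers a planted principal subspace", {
  set.seed(8)
  m <- 10
  basis <- qr.Q(qr(matrix(rnorm(m * 2), m)))  # random 2-D subspace
  scores <- ar1_stream(30000, 2, c(1, 0.6))
  X <- scores %*% t(basis) + matrix(rnorm(30000 * m, sd = 0.05), ncol = m)
  net <- lahn_init(2, m, seed = 8)
  fit <- lahn_train(net, X)
  # principal angle between span(q) and the planted subspace
  qb <- qr.Q(qr(t(fit$net$q)))
  sv <- svd(t(qb) %*% basis)$d
  angle <- acos(min(pmin(sv, 1))) * 180 / pi
  expect_lt(angle, 5)
})

test_that("lateral learning decorrelates responses on correlated input", {
  set.seed(9)
  # correlated 6-D stream with enough spectral spread that four neurons
  # can settle on distinct components
  m <- 6
  B <- qr.Q(qr(matrix(rnorm(m * m), m)))
  ev <- c(0.5, 0.35, 0.25, 0.18, 0.05, 0.05)
  X <- ar1_stream(10000, m, sqrt(ev)) %*% t(B)
  net <- lahn_init(4, m, seed = 9)
  fit <- lahn_train(net, X)
  early <- fit$xi[1:1000, ]
  late <- fit$xi[9001:10000, ]
  mean_abs_cor <- function(M) {
    C <- stats::cor(M)
    mean(abs(C[upper.tri(C)]))
  }
  expect_lt(mean_abs_cor(late), mean_abs_cor(early))
})

# Full model ------------------------------------------------------------------

test_that("model training is deterministic and uses 20 LAHN neurons by default", {
  env <- env_square(1.8)
  m1 <- train_grid_model(env, duration = 20, seed = 3)
  m2 <- train_grid_model(env, duration = 20, seed = 3)
  expect_identical(m1$response_log, m2$response_log)
  expect_identical(m1$lahn$q, m2$lahn$q)
  expect_identical(m1$lahn$n, 20L)
  expect_equal(nrow(m1$response_log), nrow(m1$traj))
  expect_equal(length(m1$checkpoints), 11)  # init + 10 snapshots
})

test_that("some LAHN neuron attains positive gridness in a square arena", {
  best <- vapply(1:3, function(seed) {
    m <- train_grid_model(env_square(1.8), duration = 240, seed = seed)
    resp <- replay_responses(m, "final")
    max(gridscape:::neuron_hgs(m$traj, resp, 0.01, 1, 0.25), na.rm = TRUE)
  }, numeric(1))
  expect_gt(max(best), 0)
})
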