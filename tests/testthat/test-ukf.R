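test_that("sigma points reproduce mean and covariance exactly", {
  set.seed(4)
  M <- matrix(rnorm(49), 7, 7)
  P <- M %*% t(M) + diag(7) * 0.1
  m <- rnorm(7)
  st <- augmented_state(m, P)
  sp <- sigma_points(st, ukf_config())
  rec_m <- drop(sp$points %*% sp$wm)
  d <- sweep(sp$points, 1, rec_m)
  rec_P <- d %*% diag(sp$wc) %*% t(d)
  expect_equal(rec_m, m, tolerance = 1e-12)
  expect_equal(rec_P, P, tolerance = 1e-10)

  # zero covariance: all points collapse onto the mean
  sp0 <- sigma_points(augmented_state(m, matrix(0, 7, 7)), ukf_config())
  expect_true(all(abs(sweep(sp0$points, 1, m)) < 1e-12))

  # unit spread (alpha = 1, kappa chosen so n + lambda = 1) puts points at
  # mean +/- unit axis offsets for an identity covariance
  cfg1 <- ukf_config(sigma_alpha = 1, sigma_kappa = -6)
  sp1 <- sigma_points(augmented_state(m, diag(7)), cfg1)
  expect_equal(sp1$points[, 2:8], m + diag(7), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("the continuous-discrete UKF is exact on a linear-Gaussian fixture", {
  # damped oscillator observed in position; closed-form Kalman filter is the
  # independent oracle (unscented transform is exact for linear flows)
  A <- matrix(c(0, -4, 1, -0.4), 2, 2)
  H <- c(1, 0)
  Qd <- c(0.1, 0.2)
  R <- 0.5
  dt <- 0.01
  set.seed(12)
  y <- rnorm(300)
  m0 <- c(0.3, -0.1)
  P0 <- diag(c(1, 2))
  ukf <- gaintrack:::cpp_ukf_filter(y, dt, 1L, numeric(12), A, Qd, R, H, m0, P0,
                        n_sub = 4L, alpha = 1e-2, beta = 2, kappa = 0,
                        bound = 1e6)
  orc <- kalman_oracle(y, A, H, Qd, R, dt, m0, P0)
  expect_equal(ukf$means, orc$means, tolerance = 1e-8)
  sds <- t(apply(orc$covs, 1, function(P) sqrt(diag(P))))
  expect_equal(ukf$sds, sds, tolerance = 1e-8)
})

test_that("prediction reduces to an ODE step for a degenerate sigma set", {
  p <- nmm_preset("alpha")
  eq <- find_equilibrium(p)$state
  m <- c(as.numeric(eq) + 0.1, 22)
  st <- augmented_state(m, matrix(0, 7, 7))
  cfg <- ukf_config(param_noise_var = 0, state_noise = rep(0, 6),
                    inner_dt = 1e-4)
  pred <- ukf_predict(st, p, cfg, dt = 0.02)
  # reference: fine deterministic RK integration of the augmented drift
  x <- m[1:6]
  a_i <- m[7]
  pp <- p; pp$a_i <- a_i
  h <- 1e-4
  for (i in 1:200) {
    k1 <- nmm_drift(x, pp)
    k2 <- nmm_drift(x + h / 2 * k1, pp)
    k3 <- nmm_drift(x + h / 2 * k2, pp)
    k4 <- nmm_drift(x + h * k3, pp)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(pred$mean, c(x, a_i), tolerance = 1e-9)
  expect_equal(pred$cov, matrix(0, 7, 7), tolerance = 1e-12)
})

test_that("the gain mean is invariant under prediction with zero parameter noise", {
  p <- nmm_preset("alpha")
  st <- augmented_state(c(as.numeric(find_equilibrium(p)$state), 25),
                        diag(7) * 1e-4)
  cfg <- ukf_config(param_noise_var = 0)
  pred <- ukf_predict(st, p, cfg, dt = 1 / 512)
  # a_i drifts only through its (tiny) correlation with the states built up
  # inside the step; with a near-degenerate prior it stays put
  expect_equal(pred$mean[7], 25, tolerance = 1e-6)
})

test_that("measurement-update limits behave like a Kalman gain of 0 and 1", {
  m <- c(0.1, 0, 2, 0, 1, 0, 22)
  P <- diag(7)
  st <- augmented_state(m, P)
  huge <- ukf_update(st, y = 5, ukf_config(meas_noise_var = 1e12))
  expect_equal(huge$state$mean, m, tolerance = 1e-9)
  expect_equal(huge$state$cov, P, tolerance = 1e-3)
  tiny <- ukf_update(st, y = 5, ukf_config(meas_noise_var = 1e-12))
  expect_equal(observe_state(tiny$state$mean[1:6]), 5, tolerance = 1e-6)
  expect_equal(huge$innovation, 5 - observe_state(m[1:6]))
  # posterior covariance stays PSD
  ev <- eigen(tiny$state$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("tracking is deterministic and keeps the covariance bounded", {
  sim <- quick_sim(duration = 12, seed = 8)
  r1 <- track_gain(sim$trace, nmm_preset("alpha"),
                   ukf_config(meas_noise_var = 1e-2))
  r2 <- track_gain(sim$trace, nmm_preset("alpha"),
                   ukf_config(meas_noise_var = 1e-2))
  expect_identical(r1$mean, r2$mean)
  expect_identical(r1$loglik, r2$loglik)
  # no covariance inflation on stationary data
  tr_cov <- rowSums(r1$sd^2)
  expect_lt(max(tail(tr_cov, 100)), max(head(tr_cov, 100)))
  expect_true(all(r1$innovation_var > 0))
})

test_that("a constant inhibitory gain is recovered from noisy observations", {
  p <- nmm_preset("alpha") # true gain 22
  ok <- 0
  for (seed in c(11, 12, 13)) {
    sim <- integrate_nmm(p, simulation_config(duration = 25, seed = seed),
                         burn_in = 3)
    y <- sim$trace
    y$samples <- y$samples + { set.seed(seed + 500); rnorm(length(y), 0, 0.1) }
    init <- augmented_state(c(as.numeric(find_equilibrium(p)$state), 27),
                            diag(7))
    res <- track_gain(y, p, ukf_config(meas_noise_var = 0.01), init = init)
    if (abs(tail(res$gain$samples, 1) - 22) / 22 < 0.10) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("a step change in the gain pulls the track in the right direction", {
  p <- nmm_preset("alpha")
  cfg <- simulation_config(duration = 15, seed = 14)
  a <- integrate_nmm(p, cfg, burn_in = 3)
  p2 <- p; p2$a_i <- 26
  init2 <- a$states[nrow(a$states), ]
  b <- integrate_nmm(p2, simulation_config(duration = 15, seed = 15),
                     init = init2)
  y <- trace(c(a$trace$samples, b$trace$samples), fs = 512)
  y$samples <- y$samples + { set.seed(77); rnorm(length(y), 0, 0.1) }
  res <- track_gain(y, p, ukf_config(meas_noise_var = 0.01))
  g <- res$gain$samples
  pre <- mean(g[(10 * 512):(15 * 512)])
  mid <- mean(g[(20 * 512):(25 * 512)])
  post <- mean(g[(25 * 512):(30 * 512)])
  # clear movement toward the +4 mV step (adaptation lag ~ tens of seconds
  # once the gain posterior has tightened), still rising at the end
  expect_gt(post - pre, 1)
  expect_gt(post, mid)
  expect_lt(abs(pre - 22), 0.5)
})

test_that("innovations on well-specified data are zero-mean", {
  p <- nmm_preset("alpha")
  sim <- integrate_nmm(p, simulation_config(duration = 30, seed = 19),
                       burn_in = 3)
  y <- sim$trace
  y$samples <- y$samples + { set.seed(600); rnorm(length(y), 0, 0.1) }
  res <- track_gain(y, p, ukf_config(meas_noise_var = 0.01))
  inn <- res$innovation[-(1:(5 * 512))]
  se <- sd(inn) / sqrt(length(inn))
  expect_lt(abs(mean(inn)), 3 * se)
})

test_that("tracking results round-trip to disk with a JSON summary", {
  sim <- quick_sim(duration = 4, seed = 2)
  res <- track_gain(sim$trace, nmm_preset("alpha"),
                    ukf_config(meas_noise_var = 1e-2))
  f <- tempfile(fileext = ".tsv")
  write_tracking_result(res, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), length(res$time))
  expect_equal(tab$mean_a_i, res$mean[, 7], tolerance = 1e-6)
  js <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(js$final_gain, res$mean[nrow(res$mean), 7], tolerance = 1e-9)
  unlink(c(f, paste0(f, ".json")))
})
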