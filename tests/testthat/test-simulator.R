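test_that("noiseless integration converges to the root-solver equilibrium", {
  p <- nmm_preset("alpha", c = 68) # stable low-connectivity regime
  p$input_var <- 0
  eq <- find_equilibrium(p)
  cfg <- simulation_config(duration = 10, seed = 1)
  sim <- integrate_nmm(p, cfg, init = as.numeric(eq$state) + 0.5)
  terminal <- sim$states[nrow(sim$states), ]
  expect_equal(terminal, as.numeric(eq$state), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("identical seeds give bit-identical traces; schemes cross-validate", {
  p <- nmm_preset("alpha")
  cfg <- simulation_config(duration = 10, seed = 33)
  s1 <- integrate_nmm(p, cfg)
  s2 <- integrate_nmm(p, cfg)
  expect_identical(s1$trace$samples, s2$trace$samples)

  # output variance agreement between the RK scheme at dt and
  # Euler-Maruyama at dt/10 (the step-size-invariance of the noise
  # convention is what makes this comparison meaningful)
  v_rk <- var(integrate_nmm(p, simulation_config(duration = 30, seed = 5),
                            burn_in = 3)$trace$samples)
  cfg_em <- simulation_config(dt = 1 / 20480, duration = 30, seed = 6,
                              scheme = "euler-maruyama")
  v_em <- var(integrate_nmm(p, cfg_em, burn_in = 3)$trace$samples)
  expect_lt(abs(v_rk - v_em) / v_rk, 0.10)
})

test_that("integration halts with a divergence error naming the step", {
  p <- nmm_preset("alpha")
  cfg <- simulation_config(duration = 1, seed = 1, bound = 1e-3)
  expect_error(integrate_nmm(p, cfg), "step")
})

test_that("equilibria have zero derivative components and tiny drift norm", {
  for (preset in c("alpha", "seizure", "fitted")) {
    p <- nmm_preset(preset)
    eq <- find_equilibrium(p)
    expect_lt(eq$residual, 1e-9)
    expect_equal(as.numeric(eq$state)[c(2, 4, 6)], c(0, 0, 0))
  }
})

test_that("equilibrium output increases with input below the oscillatory regime", {
  p <- nmm_preset("alpha", c = 68)
  grid <- seq(0, 120, by = 5)
  sw <- equilibrium_sweep(p, grid)
  expect_true(all(sw$converged))
  expect_true(all(diff(sw$output) > -1e-9))
})

test_that("stability flips across the oscillatory window and is grid-robust", {
  # independent eigenvalue enumeration of all equilibrium branches shows the
  # Hopf-unstable window sits near c = 135 (at c = 120 every reachable
  # branch is stable for all inputs); the sweep must find both crossings
  p <- nmm_preset("alpha", c = 135)
  sw <- equilibrium_sweep(p, seq(0, 600, length.out = 81))
  flips <- sum(diff(sw$stable[sw$converged]) != 0)
  expect_gte(flips, 1)
  # refinement does not create or destroy flips
  sw2 <- equilibrium_sweep(p, seq(0, 600, length.out = 161))
  flips2 <- sum(diff(sw2$stable[sw2$converged]) != 0)
  expect_equal(flips2, flips)
  # far below the window everything is stable
  low <- equilibrium_sweep(p, seq(0, 30, by = 5))
  expect_true(all(low$stable[low$converged]))
  # descending sweeps are supported and stay on the upper branch
  desc <- equilibrium_sweep(p, seq(600, 350, by = -25))
  expect_true(all(desc$stable[desc$converged]))
})

test_that("power spectrum resolves a pure tone and conserves variance", {
  tr <- tone_trace(10, fs = 512, dur = 16)
  psd <- power_spectrum(tr, window_s = 4)
  expect_equal(spectral_peak(psd, 1, 100), 10, tolerance = 0.26)
  set.seed(11)
  wn <- trace(rnorm(512 * 60), fs = 512)
  psd_wn <- power_spectrum(wn, window_s = 2)
  df <- psd_wn$freq[2] - psd_wn$freq[1]
  expect_equal(sum(psd_wn$power) * df, var(wn$samples), tolerance = 0.05)
  band <- psd_wn$freq >= 1 & psd_wn$freq <= 512 / 4
  expect_lt(max(psd_wn$power[band]) / min(psd_wn$power[band]), 10)
  expect_error(power_spectrum(tone_trace(5, dur = 1), window_s = 4), "short")
})

test_that("fixed parameters give stationary activity with an alpha-band peak at c = 135", {
  peaks <- c()
  for (seed in 1:3) {
    sim <- integrate_nmm(nmm_preset("alpha", c = 135),
                         simulation_config(duration = 60, seed = seed),
                         burn_in = 5)
    y <- sim$trace$samples
    n <- length(y)
    v1 <- var(y[1:(n / 2)]); v2 <- var(y[(n / 2 + 1):n])
    expect_lt(abs(v1 - v2) / max(v1, v2), 0.25)
    peaks <- c(peaks, spectral_peak(power_spectrum(sim$trace, 4), 1, 50))
  }
  expect_gte(mean(peaks >= 7 & peaks <= 14), 0.5)
})

test_that("halving the step barely changes variance and dominant frequency", {
  # common random numbers: both resolutions integrate the same Brownian
  # path, so the comparison isolates the discretization effect
  p <- nmm_preset("alpha")
  set.seed(31)
  n_fine <- 2 * 2048 * 44 # 40 s + 4 s burn-in at dt/2
  z_fine <- rnorm(n_fine)
  z_coarse <- (z_fine[seq(1, n_fine, 2)] + z_fine[seq(2, n_fine, 2)]) /
    sqrt(2)
  a <- integrate_nmm(p, simulation_config(dt = 1 / 2048, duration = 40),
                     burn_in = 4, noise = z_coarse)
  b <- integrate_nmm(p, simulation_config(dt = 1 / 4096, duration = 40),
                     burn_in = 4, noise = z_fine)
  expect_lt(abs(var(a$trace$samples) - var(b$trace$samples)) /
              var(a$trace$samples), 0.05)
  fa <- spectral_peak(power_spectrum(a$trace, 4), 1, 50)
  fb <- spectral_peak(power_spectrum(b$trace, 4), 1, 50)
  expect_lt(abs(fa - fb), 1)
})

test_that("slow gain obeys its linear closed forms with noise off", {
  p <- nmm_preset("alpha", c = 68)
  p$input_var <- 0
  # beta = 0: pure exponential decay at rate epsilon * alpha
  slow <- slow_gain_parameters(epsilon = 0.1, alpha = 0.06, beta = 0,
                               slow_noise_var = 0)
  cfg <- simulation_config(duration = 100, seed = 1, output_rate = 64)
  sim <- integrate_slow_fast(p, slow, cfg, a_i_init = 22)
  t <- (seq_along(sim$gain$samples)) / 64
  expect_equal(sim$gain$samples, 22 * exp(-0.1 * 0.06 * t), tolerance = 1e-4)

  # with coupling on and the fast system at rest, the gain settles at
  # beta * sigmoid(V) / alpha evaluated at the terminal operating point
  slow2 <- slow_gain_parameters(epsilon = 2, alpha = 0.5, beta = 1,
                                slow_noise_var = 0)
  cfg2 <- simulation_config(duration = 60, seed = 1, output_rate = 64)
  sim2 <- integrate_slow_fast(p, slow2, cfg2, a_i_init = 22)
  n <- length(sim2$gain$samples)
  a_end <- sim2$gain$samples[n]
  v_end <- sim2$trace$samples[n]
  expect_equal(a_end, slow2$beta * sigmoid(v_end, p$sigmoid) / slow2$alpha,
               tolerance = 1e-3)
  # and the terminal slow derivative is ~0
  expect_lt(abs(diff(tail(sim2$gain$samples, 2))) * 64, 1e-3)
})

test_that("freezing the slow equation reproduces the fixed-gain integration exactly", {
  p <- nmm_preset("seizure")
  slow0 <- slow_gain_parameters(epsilon = 1e-300, alpha = 0.06, beta = 5,
                                slow_noise_var = 0)
  cfg <- simulation_config(duration = 5, seed = 9)
  a <- integrate_slow_fast(p, slow0, cfg, a_i_init = p$a_i)
  b <- integrate_nmm(p, cfg)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_true(all(a$gain$samples == p$a_i))
})

test_that("the slow-fast model generates seizure transitions with a DC shift", {
  n_ok <- 0
  for (seed in 1:3) {
    sim <- integrate_slow_fast(nmm_preset("seizure"), slow_gain_parameters(),
                               simulation_config(duration = 120, seed = seed))
    wv <- window_variances(sim$trace)
    if (max(wv) / median(wv) > 5) n_ok <- n_ok + 1
    # gain climbs out of the ictal band: a genuine infraslow trajectory
    expect_gt(max(sim$gain$samples) - min(sim$gain$samples), 2)
  }
  expect_gte(n_ok, 2)
})

test_that("trace round-trips through the text container at full precision", {
  sim <- quick_sim(duration = 2)
  f <- tempfile(fileext = ".tsv")
  write_trace(sim$trace, f, seed = 1)
  back <- read_trace(f)
  expect_equal(back$samples, sim$trace$samples, tolerance = 1e-14)
  expect_identical(back$fs, sim$trace$fs)
  expect_identical(back$kind, sim$trace$kind)
  unlink(f)
})
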