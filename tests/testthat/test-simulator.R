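# Simulation tests run at coarse discretization and short distances; the
# long-run behaviour is covered by the acceptance suite.

near_uniform_gradient <- function(delta = 0.1) {
  # an essentially flat thickness field expressed in the gradient family
  wall_gradient("pearson", delta * (1 - 1e-6), delta, 1e5)
}

test_that("a uniformly stressed spherical cap grows as a sphere", {
  R <- 2
  prof <- quarter_sphere(R = R, spacing = 0.05, frac = 0.8)
  pars <- viscoplastic_params(P = 0.5, Phi = 5e-3, sigma_y = 2,
                              v_tip = 2.5 / 60)
  cfg <- sim_config(pars, near_uniform_gradient(0.05), spacing = 0.05,
                    tip_step = 0.05, record_every = Inf,
                    target_distance = 0.5)
  # sigma = PR/(2 delta) = 10 MPa > sigma_y: uniform normal velocity
  st <- tipwall:::growth_step(prof$x, prof$r, cfg)
  expect_false(st$stalled)
  # the stepped shape is still a sphere, with a larger radius
  centre_x <- prof$x[1] - R
  rad <- sqrt((st$x - centre_x)^2 + st$r^2)
  expect_lt(diff(range(rad[seq_len(length(rad) - 3)])), 2e-3)
  expect_gt(mean(rad), R)
})

test_that("growth stalls cleanly when the yield threshold exceeds stress", {
  prof <- ref_profile_coarse()
  pars <- viscoplastic_params(Phi = 2.5e-3, sigma_y = 100)
  cfg <- sim_config(pars, paper_gradient(), spacing = 0.15,
                    tip_step = 0.15, record_every = Inf, target_distance = 1)
  sim <- simulate_tip_growth(prof, cfg)
  expect_true(sim$stalled)
  expect_equal(sim$advance, 0)
})

test_that("residual distance weights dome points and handles exact matches", {
  prof <- ref_profile_coarse()
  xy <- cbind(x = prof$x, r = prof$r)
  # exact translated match: rD = 0, log is -Inf
  moved <- xy; moved[, "x"] <- moved[, "x"] + 3
  rd0 <- residual_distance(moved, xy, translation = 3, spacing = 0.15)
  expect_equal(rd0$rD, 0)
  expect_identical(rd0$log_rD, -Inf)
  # uniform offset: rD equals the offset regardless of the weights
  off <- xy; off[, "x"] <- off[, "x"] + 0.01
  rd1 <- residual_distance(off, xy, translation = 0, half_width = 1,
                           spacing = 0.15)
  rd2 <- residual_distance(off, xy, translation = 0, half_width = 5,
                           spacing = 0.15)
  expect_equal(rd1$rD, 0.01, tolerance = 1e-12)
  expect_equal(rd2$rD, 0.01, tolerance = 1e-12)
  # a shank-only distortion is discounted by the dome weight
  shank <- xy; shank[200:nrow(shank), "r"] <-
    shank[200:nrow(shank), "r"] + 0.1
  rd3 <- residual_distance(shank, xy, spacing = 0.15)
  expect_lt(rd3$rD, 0.001)
})

test_that("simulated tip advance accumulates time consistently", {
  prof <- ref_profile_coarse()
  pars <- viscoplastic_params(Phi = 4.3e-3, sigma_y = 10.1)
  cfg <- sim_config(pars, paper_gradient(), spacing = 0.15,
                    tip_step = 0.15, record_every = 0.5,
                    target_distance = 1.5)
  sim <- simulate_tip_growth(prof, cfg)
  expect_false(sim$stalled)
  expect_gte(sim$advance, 1.5)
  expect_true(all(diff(sim$tip_positions) >= 0))
  expect_true(all(diff(sim$frame_times) >= 0))
  # implied tip speed of the order of the observed one
  expect_equal(sim$advance / sim$elapsed, 2.5 / 60, tolerance = 0.25)
  # frames recorded roughly every record_every of advance
  expect_gte(length(sim$frames), 3)
})

test_that("doubling extensibility doubles the growth rate, same shape", {
  prof <- ref_profile_coarse()
  g <- paper_gradient()
  run <- function(phi) {
    pars <- viscoplastic_params(Phi = phi, sigma_y = 10.1)
    cfg <- sim_config(pars, g, spacing = 0.15, tip_step = 0.15,
                      record_every = Inf, target_distance = 2)
    simulate_tip_growth(prof, cfg)
  }
  a <- run(4.3e-3)
  b <- run(8.6e-3)
  # the strain-rate field scales with Phi: time halves, trajectory is the
  # same up to time reparameterization
  expect_equal(b$elapsed, a$elapsed / 2, tolerance = 1e-3)
  rd <- residual_distance(b$final, a$final, translation = 0,
                          spacing = 0.15)
  expect_lt(rd$rD, 1e-3)
})

test_that("a parameter grid scan brackets its own minimum", {
  prof <- ref_profile_coarse()
  pars <- viscoplastic_params(Phi = 4.3e-3, sigma_y = 10.1)
  cfg <- sim_config(pars, paper_gradient(), spacing = 0.15,
                    tip_step = 0.15, record_every = Inf, target_distance = 2)
  out <- scan_parameters(prof, cfg, phi_grid = c(3e-3, 4.3e-3),
                         sigma_y_grid = c(10.1, 100))
  expect_equal(dim(out), c(2L, 2L))
  # the stalled column is +Inf
  expect_true(all(is.infinite(out[, 2])))
  expect_true(all(is.finite(out[, 1])))
})

test_that("profiles can be extended with an analytic cylinder", {
  prof <- ref_profile()
  ext <- extend_profile(prof, 80)
  expect_gte(max(ext$s), 80)
  n <- nrow(ext)
  expect_equal(ext$r[n], tail(prof$r, 1))
  expect_equal(ext$phi[n], pi / 2)
  expect_true(validate_profile(ext))
  expect_identical(extend_profile(prof, 10), prof)
})
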