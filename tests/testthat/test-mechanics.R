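test_that("thin-shell stresses obey the cylinder and sphere limits", {
  # cylinder r = 1, delta = 0.1, P = 0.5: sigma_s = 2.5, sigma_theta = 5
  cyl <- meridional_profile(s = 0:10, x = -(0:10), r = rep(1, 11),
                            phi = rep(pi / 2, 11), kappa_s = rep(0, 11),
                            kappa_theta = rep(1, 11), spacing = 1)
  st <- shell_stresses(cyl, rep(0.1, 11), 0.5)
  expect_equal(st$sigma_s, rep(2.5, 11))
  expect_equal(st$sigma_theta, rep(5, 11))
  expect_equal(st$sigma_theta, 2 * st$sigma_s, tolerance = 1e-6)

  # sphere R = 2, delta = 0.05, P = 0.5: both stresses 10
  sph <- quarter_sphere(R = 2, spacing = 0.01, frac = 0.9)
  st2 <- shell_stresses(sph, rep(0.05, nrow(sph)), 0.5)
  expect_equal(st2$sigma_s, rep(10, nrow(sph)), tolerance = 1e-3)
  expect_equal(st2$sigma_theta, st2$sigma_s, tolerance = 1e-3)

  expect_error(shell_stresses(cyl, rep(0, 11), 0.5), "positive")
})

test_that("stress scales inversely with thickness and linearly with turgor", {
  prof <- ref_profile()
  g <- paper_gradient()
  delta <- evaluate_gradient(g, prof$s)
  a <- shell_stresses(prof, delta, 0.495)
  b <- shell_stresses(prof, 2 * delta, 0.495)
  cc <- shell_stresses(prof, delta, 0.99)
  expect_equal(a$sigma_s, 2 * b$sigma_s, tolerance = 1e-12)
  expect_equal(cc$sigma_theta / a$sigma_theta,
               rep(2, nrow(prof)), tolerance = 1e-12)
})

test_that("effective stress reduces correctly in special cases", {
  expect_equal(effective_stress(10, 10, 0.5), 10)
  expect_equal(effective_stress(2.5, 5, 0.5), sqrt(18.75))
  expect_equal(effective_stress(3, 0, 0.5), 3)
  expect_equal(effective_stress(-3, 0, 0.5), 3)
  expect_error(effective_stress(NaN, 1), "finite")
})

test_that("self-similar normal velocity is the axial-translation projection", {
  prof <- ref_profile()
  vn <- normal_velocity_selfsimilar(prof, 2.5 / 60)
  expect_equal(vn[1], 2.5 / 60)
  expect_equal(vn, 2.5 / 60 * cos(prof$phi))
  p3 <- meridional_profile(0, 0, 0, pi / 3, 1, 1, spacing = 1)
  expect_equal(normal_velocity_selfsimilar(p3, 1), 0.5)
})

test_that("the expected strain rate has the documented tip limit and zeros", {
  # sphere cap: at the tip eps* = 2 K kappa v
  sph <- quarter_sphere(R = 1 / 0.3, spacing = 0.01, frac = 0.9)
  st <- shell_stresses(sph, rep(0.05, nrow(sph)), 0.5)
  se <- effective_stress(st$sigma_s, st$sigma_theta, 0.5)
  vn <- normal_velocity_selfsimilar(sph, 0.0417)
  eps <- expected_strain_rate(sph, st$sigma_s, st$sigma_theta, se, vn)
  expect_equal(eps[1], 2 * 0.3 * 0.0417, tolerance = 1e-3)
  # zero where the wall does not move
  vn0 <- vn; vn0[10:20] <- 0
  eps0 <- expected_strain_rate(sph, st$sigma_s, st$sigma_theta, se, vn0)
  expect_true(all(eps0[10:20] == 0))
})

test_that("Lockhart regression identifies exact and noisy laws", {
  sigma <- seq(11.5, 17, by = 0.1)
  eps <- 0.0025 * (sigma - 11)
  lk <- lockhart_fit(sigma, eps)
  expect_equal(lk$Phi, 2.5e-3, tolerance = 1e-10)
  expect_equal(lk$sigma_y, 11, tolerance = 1e-7)
  expect_equal(lk$r2, 1)

  # 2% multiplicative noise: parameters recovered within 5% across seeds
  set.seed(99)
  rel <- replicate(300, {
    e2 <- eps * exp(rnorm(length(eps), 0, 0.02))
    fit <- lockhart_fit(sigma, e2)
    c(abs(fit$Phi - 2.5e-3) / 2.5e-3, abs(fit$sigma_y - 11) / 11)
  })
  expect_lt(mean(rel[1, ]), 0.05)
  expect_lt(mean(rel[2, ]), 0.05)
  expect_lt(stats::quantile(rel[1, ], 0.95), 0.10)

  set.seed(7)
  eps_rev <- rev(eps) + runif(length(eps), 0, 2e-4)
  expect_warning(lockhart_fit(sigma, eps_rev), "non-Lockhart")
  expect_error(lockhart_fit(sigma[1:3], eps[1:3]), "5 points")
})

test_that("the dome stress/strain relation follows a single Lockhart line", {
  prof <- ref_profile()
  mech <- mechanical_state(prof, paper_gradient(), paper_params())
  expect_equal(max(mech$sigma_e),
               0.495 / (2 * evaluate_gradient(paper_gradient(), 0) *
                          prof$kappa_s[1]), tolerance = 1e-2)
  lk <- lockhart_fit(mech$sigma_e, mech$eps_star)
  expect_gt(lk$r2, 0.9)
  expect_gt(lk$Phi, 0)
  expect_gt(lk$sigma_y, 0)
})

test_that("equal partition reproduces the strain rate product exactly", {
  sigma <- c(3, 5, 8)
  eps <- c(0.04, 0.09, 0)
  pw <- pollen_wall_properties(sigma, eps)
  expect_equal(pw$Phi, sqrt(eps))
  expect_equal(pw$Phi * (sigma - pw$sigma_y), eps)
  expect_equal(pw$Phi[3], 0)
  expect_equal(pw$sigma_y[3], 8)
  expect_equal(pw$Phi[1], 0.2)
  expect_equal(pw$sigma_y[1], 2.8)
  expect_error(pollen_wall_properties(1, -0.1), "non-negative")
})

test_that("reduced turgor with faster growth shifts the inferred plasticity", {
  prof <- ref_profile()
  g <- paper_gradient()
  ctrl <- mechanical_state(prof, g, viscoplastic_params(P = 0.495,
                                                        v_tip = 2.5 / 60))
  aux <- mechanical_state(prof, g, viscoplastic_params(P = 0.186,
                                                       v_tip = 2 * 2.5 / 60))
  lk_c <- lockhart_fit(ctrl$sigma_e, ctrl$eps_star)
  lk_a <- lockhart_fit(aux$sigma_e, aux$eps_star)
  expect_gt(lk_a$Phi, lk_c$Phi)
  expect_lt(lk_a$sigma_y, lk_c$sigma_y)
  # scaling laws: sigma_y ~ P and Phi ~ v/P
  expect_equal(lk_a$sigma_y / lk_c$sigma_y, 0.186 / 0.495, tolerance = 1e-6)
  expect_equal(lk_a$Phi / lk_c$Phi, 2 * 0.495 / 0.186, tolerance = 1e-6)
})
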