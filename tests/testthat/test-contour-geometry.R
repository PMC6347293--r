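test_that("contour tables are read per cell with format checking", {
  f <- withr::local_tempfile(fileext = ".csv")
  pts <- circle_points(R = 3, by = 0.2)
  tab <- data.frame(cell_id = rep(c("a", "b"), each = nrow(pts)),
                    u = c(pts[, 1], pts[, 1] + 1), v = c(pts[, 2], pts[, 2]))
  write.csv(tab, f, row.names = FALSE)
  cts <- read_contours(f)
  expect_length(cts, 2L)
  expect_equal(cts[["a"]]$points[, "u"], pts[, 1], ignore_attr = TRUE)
  expect_equal(nrow(cts[["b"]]$points), nrow(pts))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[c("cell_id", "u")], f2, row.names = FALSE)
  expect_error(read_contours(f2), "missing column")

  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[1:10, ], f3, row.names = FALSE)
  expect_error(read_contours(f3), "fewer than 20")
})

test_that("resampling returns exactly equidistant points on the curve", {
  pts <- circle_points(R = 3, by = 0.2)
  rs <- smooth_and_resample(pts, spacing = 0.05, smoothing = 0)
  d <- sqrt(diff(rs[, 1])^2 + diff(rs[, 2])^2)
  expect_lt(max(abs(d - 0.05)), 1e-6)
  radial <- sqrt(rs[, 1]^2 + rs[, 2]^2)
  expect_lt(max(abs(radial - 3)), 1e-3)
  expect_error(smooth_and_resample(pts, spacing = 0), "positive")
  expect_error(smooth_and_resample(pts, spacing = 10), "tenth")
})

test_that("smoothing a jittered circle reduces deviation below the jitter", {
  sdj <- 0.05
  pts <- circle_points(R = 3, by = 0.2, jitter = sdj, seed = 42)
  rs <- smooth_and_resample(pts, spacing = 0.05)
  radial <- sqrt(rs[, 1]^2 + rs[, 2]^2)
  interior <- seq(4, length(radial) - 3)
  expect_lt(max(abs(radial[interior] - 3)), sdj)
  expect_lt(max(abs(radial - 3)), 2 * sdj)
})

test_that("discrete curvature matches closed forms", {
  # circle of radius 2: kappa = 0.5 everywhere
  pts <- smooth_and_resample(circle_points(R = 2, by = 0.1), spacing = 0.05,
                             smoothing = 0)
  kap <- meridional_curvature(pts, spacing = 0.05)
  expect_lt(max(abs(abs(kap) - 0.5)), 1e-3)

  # straight line: kappa = 0
  line <- cbind(u = seq(0, 5, by = 0.05), v = 0.5 * seq(0, 5, by = 0.05))
  rs <- smooth_and_resample(line, spacing = 0.05, smoothing = 0)
  expect_lt(max(abs(meridional_curvature(rs, spacing = 0.05))), 1e-6)

  # parabola v = u^2 near its apex: kappa(0) = 2
  u <- seq(-1, 1, by = 0.01)
  par_pts <- smooth_and_resample(cbind(u = u, v = u^2), spacing = 0.02,
                                 smoothing = 0)
  kap_p <- meridional_curvature(par_pts, spacing = 0.02)
  tip <- find_tip(par_pts, spacing = 0.02)
  i0 <- round(tip / 0.02) + 1L
  expect_lt(abs(abs(kap_p[i0]) - 2), 1e-2)

  expect_error(meridional_curvature(par_pts[1:4, ]), "5 points")
})

test_that("window averaging pools both sides and is order-invariant", {
  s <- (-100:100) * 0.05
  kap <- 0.4 * exp(-(s / 3)^2)
  one <- data.frame(s = s, kappa = kap)
  avg <- average_curvature_profile(list(one, one, one))
  # identical series: the pooled mean reproduces the window average
  expect_equal(avg$kappa_mean[1], mean(kap[abs(s) <= 0.1]))
  # constant identical series: pooled sd is exactly zero
  flat <- data.frame(s = s, kappa = rep(0.3, length(s)))
  avg_f <- average_curvature_profile(list(flat, flat, flat))
  expect_lt(max(avg_f$kappa_sd), 1e-6)
  expect_equal(avg_f$kappa_mean, rep(0.3, nrow(avg_f)))

  two <- data.frame(s = s, kappa = kap * 1.2)
  expect_identical(average_curvature_profile(list(one, two)),
                   average_curvature_profile(list(two, one)))

  # an antisymmetric disturbance cancels in the two-sided fold
  asym <- data.frame(s = s, kappa = kap + 0.05 * sign(s))
  avg_a <- average_curvature_profile(list(asym))
  expect_equal(avg_a$kappa_mean, avg$kappa_mean, tolerance = 1e-12)
})

test_that("profile reconstruction reproduces spheres and cylinders", {
  R <- 2
  prof <- quarter_sphere(R = R, spacing = 0.01, frac = 1)
  # on a sphere phi = s / R exactly and both curvatures equal 1/R
  expect_equal(prof$phi, prof$s / R, tolerance = 1e-9)
  expect_equal(prof$r, R * sin(prof$s / R), tolerance = 1e-6)
  expect_lt(max(abs(prof$kappa_theta - 1 / R)), 1e-3)

  # hemisphere blended into a cylinder: kappa_s jumps to 0, the shank is a
  # cylinder of the sphere radius (tolerances reflect the discretized
  # curvature discontinuity at the junction)
  sc <- sphere_cylinder(R = R, shank = 5, spacing = 0.01)
  cyl <- sc$s > pi * R / 2 + 0.2
  expect_lt(max(abs(sc$kappa_theta[cyl] - 1 / R)), 3e-3)
  expect_lt(max(abs(sc$r[cyl] - R)), 1e-2)
  expect_lt(max(abs(sc$kappa_s[cyl])), 1e-6)
  expect_error(reconstruct_profile(c(0, 1), c(-0.1, 0.2)), "positive")
})

test_that("curvature and reconstruction round-trip on analytic shapes", {
  prof <- quarter_sphere(R = 3, spacing = 0.02, frac = 0.9)
  # measure curvature from the (u, v) realization of the profile and rebuild
  pts <- cbind(u = prof$r, v = prof$x)
  kap <- abs(meridional_curvature(pts, spacing = 0.02))
  rebuilt <- reconstruct_profile(prof$s, kap, spacing = 0.02)
  expect_lt(max(abs(rebuilt$r - prof$r)), 1e-3)
  expect_lt(max(abs(rebuilt$x - prof$x)), 1e-3)
  expect_lt(abs(rebuilt$kappa_theta[2] / rebuilt$kappa_s[2] - 1), 1e-2)
})

test_that("the averaged synthetic contour recovers the true dome", {
  mc <- ref_contours()
  ra <- ref_avg_profile()
  truth <- mc$truth
  # tip curvature within 5% of truth
  expect_lt(abs(ra$avg$kappa_mean[1] - truth$kappa_s[1]) / truth$kappa_s[1],
            0.05)
  # mean curvature within 2 pooled sd of truth everywhere the sd is formed
  kfun <- splinefun(truth$s, truth$kappa_s)
  sel <- ra$avg$n > 3 & ra$avg$s <= max(truth$s)
  dev <- abs(ra$avg$kappa_mean[sel] - kfun(ra$avg$s[sel]))
  band <- 2 * pmax(ra$avg$kappa_sd[sel], 1e-3)
  expect_true(all(dev <= band))
  # reconstructed shank radius close to the true cylinder radius
  expect_equal(tail(ra$profile$r, 1), 3.27, tolerance = 0.05)
})

test_that("profile invariants hold for generated and reconstructed domes", {
  for (p in list(ref_profile(), ref_avg_profile()$profile)) {
    expect_true(validate_profile(p))
    expect_true(all(p$kappa_theta >= 0))
  }
})
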