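test_that("langevin sampler is deterministic given a seed and exact at kT = 0", {
  pot <- harmonic_potential(k = 2, center = c(1, -1))
  # zero gradient at the minimum, kT = 0: stays put exactly
  traj <- run_langevin(pot, c(1, -1), dt = 0.01, kT = 0, n_steps = 50)
  expect_true(all(traj[, 1] == 1 & traj[, 2] == -1))
  t1 <- run_langevin(pot, c(0, 0), dt = 0.01, kT = 1, n_steps = 200, seed = 7)
  t2 <- run_langevin(pot, c(0, 0), dt = 0.01, kT = 1, n_steps = 200, seed = 7)
  expect_identical(t1, t2)
  t3 <- run_langevin(pot, c(0, 0), dt = 0.01, kT = 1, n_steps = 200, seed = 8)
  expect_false(identical(t1, t3))
  expect_error(run_langevin(pot, c(0, 0), dt = -1, kT = 1, n_steps = 1),
               "positive")
})

test_that("langevin sampling satisfies equipartition in a harmonic well", {
  k <- 4; kT <- 1
  pot <- harmonic_potential(k = k, center = 0)
  traj <- run_langevin(pot, 0, dt = 0.005, gamma = 1, kT = kT,
                       n_steps = 2e5, seed = 42)
  x <- traj[-(1:2000), 1]
  v_obs <- var(x)
  # Euler-Maruyama stationary variance: (kT/k) / (1 - k dt / (2 gamma))
  v_exp <- (kT / k) / (1 - k * 0.005 / 2)
  tau <- 1 / (k * 0.005)                 # correlation time in steps
  n_eff <- length(x) / (2 * tau)
  se <- v_exp * sqrt(2 / n_eff)
  expect_lt(abs(v_obs - v_exp), 3 * se)
})

test_that("curved-valley potential has a flat tilted floor and exact gradient", {
  pot <- curved_valley_potential(radius = 3, width_k = 25, tilt = 2.5)
  # valley floor: energy equals the tilt ramp only
  fl <- valley_floor(pot, seq(0, 1, length.out = 11))
  e_floor <- apply(fl, 1, pot$energy)
  expect_equal(e_floor, seq(2.5, 0, length.out = 11), tolerance = 1e-12)
  # endpoints differ by exactly the tilt
  expect_equal(pot$energy(fl[1, ]) - pot$energy(fl[11, ]), 2.5)
  # finite-difference gradient check at 100 random points near the valley
  set.seed(50)
  for (i in 1:100) {
    x <- drop(valley_floor(pot, runif(1))) + rnorm(2, sd = 0.3)
    expect_equal(pot$gradient(x), fd_gradient(pot$energy, x),
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
  # the single-well variant is minimized at angle0 along the floor
  potw <- curved_valley_potential(radius = 3, width_k = 25, angle_k = 2)
  ew <- apply(valley_floor(potw, seq(0, 1, length.out = 101)), 1, potw$energy)
  expect_equal(which.min(ew), 51)
})

test_that("synthetic ensembles lie on the requested path and reproduce by seed", {
  a <- c(-2, 0, 1); b <- c(2, 1, 0)
  ens0 <- make_synthetic_ensemble(a, b, n_frames = 200, shape = "arc",
                                  bulge = 1, sigma = 0, seed = 3)
  tp <- attr(ens0, "true_path")
  exact <- tp(attr(ens0, "path_t"))
  expect_equal(pathfe:::frame_matrix(ens0), exact, tolerance = 1e-12)
  # line shape with sigma = 0: frames exactly on the segment
  ensl <- make_synthetic_ensemble(a, b, n_frames = 50, shape = "line",
                                  sigma = 0, seed = 3)
  lam <- line_project(pathfe:::frame_matrix(ensl), a, b)
  recon <- outer(lam, b - a) + rep(a, each = 50)
  expect_equal(pathfe:::frame_matrix(ensl), recon, tolerance = 1e-12)
  # determinism
  e1 <- make_synthetic_ensemble(a, b, n_frames = 100, sigma = 0.4, seed = 9)
  e2 <- make_synthetic_ensemble(a, b, n_frames = 100, sigma = 0.4, seed = 9)
  expect_identical(unclass(e1)[, ], unclass(e2)[, ])
})

test_that("pathway construction recovers the generating arc from noisy frames", {
  # protein-scale geometry: 40 A chord, 12 A bulge, 0.5 A coordinate noise
  ends <- rbind(c(-20, 0), c(20, 0))
  sig <- 0.5
  ens <- make_synthetic_ensemble(ends[1, ], ends[2, ], n_frames = 5000,
                                 shape = "arc", bulge = 12, sigma = sig,
                                 seed = 15)
  nodes <- bin_and_average(ens, ends[1, ], ends[2, ], n_bins = 50)
  cv <- reparametrize(fit_curve(nodes, P = 1))
  # fitted curve at the node parameters vs the generating arc, within
  # 3 per-node standard errors (sigma * sqrt(D) / sqrt(count))
  pts <- path_eval(cv, seq(0, 1, length.out = nrow(nodes$nodes)))
  d <- oracle_path_distance(pts, attr(ens, "true_path"))
  bound <- 3 * sig * sqrt(2) / sqrt(nodes$counts) + 0.05
  expect_true(all(d < bound))
})

test_that("quadrature oracle matches analytic marginals and converges", {
  # isotropic harmonic potential, straight-line curve through the minimum:
  # the projected free energy is quadratic with the potential's curvature
  k <- 2
  pot <- harmonic_potential(k = k, center = c(0, 0))
  seg <- reparametrize(path_curve(rbind(c(-2.5, 0), c(5, 0)), P = 0))
  ref <- reference_free_energy(pot, seg, alpha_bins = 50, kT = 1,
                               grid_n = 260, padding = 3)
  xg <- (ref$alpha - 0.5) * 5          # curve parameter to coordinate
  ok <- abs(xg) <= 1.8
  resid <- ref$free_energy[ok] - 0.5 * k * xg[ok]^2
  resid <- resid - mean(resid)
  expect_rms_lt(resid, 0.02 * 0.5 * k * 1.8^2)
  # flat potential in a box: constant profile away from the box edges
  flat <- toy_potential(function(x) 0, function(x) c(0, 0), 2)
  reff <- reference_free_energy(flat, seg, alpha_bins = 40, kT = 1,
                                grid_n = 200, padding = 1)
  mid <- reff$free_energy[reff$alpha > 0.15 & reff$alpha < 0.85]
  expect_lt(max(mid) - min(mid), 0.05)
  # grid-resolution self-check passes at adequate resolution
  expect_no_error(reference_free_energy(pot, seg, alpha_bins = 30, kT = 1,
                                        grid_n = 240, padding = 3,
                                        check = TRUE, check_tol = 0.05))
})

test_that("boltzmann_sample_1d reproduces moments of known densities", {
  # harmonic: variance kT/k
  s <- boltzmann_sample_1d(function(x) 0.5 * 8 * x^2, 2e5,
                           range = c(-3, 3), kT = 1, seed = 12)
  expect_equal(var(s), 1 / 8, tolerance = 0.02)
  expect_equal(mean(s), 0, tolerance = 0.01)
  s2 <- boltzmann_sample_1d(function(x) 0.5 * 8 * x^2, 1000,
                            range = c(-3, 3), kT = 1, seed = 12)
  s3 <- boltzmann_sample_1d(function(x) 0.5 * 8 * x^2, 1000,
                            range = c(-3, 3), kT = 1, seed = 12)
  expect_identical(s2, s3)
})

test_that("the Monte-Carlo oracle branch handles higher dimensions", {
  # 4D isotropic harmonic well, straight curve through the minimum along
  # the first axis: profile is quadratic up to MC noise
  k <- 2
  pot <- harmonic_potential(k = k, center = c(0, 0, 0, 0))
  seg <- reparametrize(path_curve(rbind(c(-2, 0, 0, 0), c(4, 0, 0, 0)),
                                  P = 0))
  ref <- reference_free_energy(pot, seg, alpha_bins = 20, kT = 1,
                               grid_n = 40, padding = 2.5,
                               mc_samples = 4e4, seed = 5)
  expect_match(attr(ref, "resolution"), "MC")
  xg <- (ref$alpha - 0.5) * 4
  ok <- abs(xg) <= 1.2
  resid <- ref$free_energy[ok] - 0.5 * k * xg[ok]^2
  resid <- resid - mean(resid)
  expect_rms_lt(resid, 0.15)
})
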