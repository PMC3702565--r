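test_that("line_project returns the orthogonal line coordinate", {
  a <- c(0, 0, 0, 0); b <- c(2, 0, 0, 0)
  expect_equal(line_project(a, a, b), 0)
  expect_equal(line_project(b, a, b), 1)
  # midpoint plus any perpendicular offset
  expect_equal(line_project(c(1, 3, -2, 0.5), a, b), 0.5)
  # grid-search oracle, D = 12
  set.seed(12)
  aa <- rnorm(12); bb <- rnorm(12); x <- rnorm(12)
  lam <- line_project(x, aa, bb)
  grid <- seq(-2, 3, by = 1e-5)
  d2 <- vapply(grid, function(l) sum((x - aa - l * (bb - aa))^2), numeric(1))
  expect_equal(lam, grid[which.min(d2)], tolerance = 2e-5)
  expect_error(line_project(x, aa, aa), "degenerate")
})

test_that("bin_and_average groups frames by line segment and averages", {
  # one frame exactly at each of 100 bin centers on the line
  a <- c(0, 0); b <- c(1, 0)
  lam <- seq(0.005, 0.995, by = 0.01)
  frames <- cbind(lam, 0)
  nodes <- bin_and_average(ensemble(frames), a, b, n_bins = 100)
  expect_equal(nrow(nodes$nodes), 100)
  expect_equal(nodes$nodes, frames, ignore_attr = TRUE, tolerance = 1e-12)
  # symmetric off-line pairs cancel to bin centers of mass
  frames2 <- rbind(cbind(lam, 0.7), cbind(lam, -0.7))
  nodes2 <- bin_and_average(ensemble(frames2), a, b, n_bins = 100)
  expect_equal(max(abs(nodes2$nodes[, 2])), 0, tolerance = 1e-12)
  expect_error(bin_and_average(ensemble(rbind(a, a) + 1), a, b), "zero projection")
})

test_that("bin averages track a known semicircular path within noise", {
  # protein-scale semicircle (radius 20 A), 0.3 A coordinate noise
  ends <- rbind(c(-20, 0, 0), c(20, 0, 0))
  sig <- 0.3
  ens <- make_synthetic_ensemble(ends[1, ], ends[2, ], n_frames = 5000,
                                 shape = "semicircle", sigma = sig, seed = 8)
  nodes <- bin_and_average(ens, ends[1, ], ends[2, ], n_bins = 50)
  d <- oracle_path_distance(nodes$nodes, attr(ens, "true_path"))
  # per-node standard error sigma * sqrt(3) / sqrt(count), plus the
  # within-bin arc-sag bias (largest in the wide end bins where the
  # chord projection compresses)
  theta_bin <- sqrt(4 * 1 / 50)               # end-bin angular width
  sag <- 20 * theta_bin^2 / 8
  bound <- 3 * sig * sqrt(3) / sqrt(pmax(nodes$counts, 1)) + sag
  expect_true(all(d < bound))
})

test_that("fit_curve recovers representable curves to machine precision", {
  # collinear, equally spaced nodes: straight segment, zero sine modes
  nodes <- outer(seq(0, 1, length.out = 12), c(1, -2, 0.5))
  cv <- fit_curve(nodes, P = 1)
  expect_lt(max(abs(cv$coeffs[3, ])), 1e-8)
  expect_equal(drop(path_eval(cv, 1)) - drop(path_eval(cv, 0)),
               c(1, -2, 0.5), tolerance = 1e-8)
  # known coefficients, D = 6, 25 nodes, no noise
  set.seed(7)
  co <- matrix(rnorm(18), 3, 6)
  tk <- seq(0, 1, length.out = 25)
  cv2 <- fit_curve(cbind(1, tk, sin(pi * tk)) %*% co, P = 1)
  expect_lt(cv2$objective, 1e-10)
  expect_lt(max(abs(cv2$coeffs - co)), 1e-6)
  expect_error(fit_curve(nodes[1:2, ], P = 1), "nodes")
})

test_that("fit_curve converges on the 100-node single-mode configuration", {
  # the production layout: M + 1 = 100 bin averages, P = 1
  ends <- rbind(c(-3, 0), c(3, 0))
  ens <- make_synthetic_ensemble(ends[1, ], ends[2, ], n_frames = 3000,
                                 shape = "arc", bulge = 1.5, sigma = 0.2,
                                 seed = 4)
  nodes <- bin_and_average(ens, ends[1, ], ends[2, ], n_bins = 100)
  cv <- fit_curve(nodes, P = 1)
  expect_true(cv$converged)
  expect_lt(cv$iterations, 500)
})

test_that("arc_length matches closed forms and the dense polyline oracle", {
  seg <- path_curve(rbind(c(0, 0, 0), c(3, 4, 0)), P = 0)
  expect_equal(arc_length(seg, 1), 5, tolerance = 1e-10)
  expect_equal(seg$L, 5, tolerance = 1e-9)
  cv <- random_test_curve(d = 5, P = 2, seed = 31)
  expect_equal(arc_length(cv, 1), oracle_polyline_length(cv),
               tolerance = 1e-6)
  expect_error(arc_length(cv, 1.5), "0, 1")
})

test_that("fitted-curve length of a planar unit semicircle approaches pi", {
  # dense noise-free semicircle nodes, generous basis
  tg <- seq(0, 1, length.out = 80)
  nodes <- cbind(cos(pi * (1 - tg)), sin(pi * (1 - tg)))
  cv <- fit_curve(nodes, P = 3, tol = 1e-9, max_iter = 3000)
  expect_equal(cv$L, pi, tolerance = 2e-3)
})

test_that("reparametrization yields constant speed and fixes stretched curves", {
  # already constant-speed straight segment: unchanged
  seg <- reparametrize(path_curve(rbind(c(1, 1), c(2, -1)), P = 0))
  ag <- seq(0, 1, length.out = 21)
  expect_equal(path_eval(seg, ag),
               outer(ag, c(2, -1)) + rep(c(1, 1), each = 21),
               tolerance = 1e-10, ignore_attr = TRUE)
  # straight segment with sinusoidally stretched parametrization:
  # Z(t) = a + (t + 0.2 sin(pi t)) * (b - a); after reparametrization the
  # midpoint parameter maps to the geometric midpoint
  ab <- c(2, -1, 3)
  co <- rbind(c(0, 0, 0), ab, 0.2 * ab)
  stretched <- reparametrize(path_curve(co, P = 1))
  expect_equal(drop(path_eval(stretched, 0.5)), ab / 2, tolerance = 1e-6)
  # speed within 1e-3 * L at 1001 parameter values (numeric differentiation)
  cv <- random_test_curve(d = 4, P = 2, seed = 9)
  h <- 1e-5
  aa <- seq(h, 1 - h, length.out = 1001)
  sp <- sqrt(rowSums((path_eval(cv, aa + h) - path_eval(cv, aa - h))^2)) / (2 * h)
  expect_lt(max(abs(sp - cv$L)), 1e-3 * cv$L)
})

test_that("tangent is the unit velocity of the reparametrized curve", {
  seg <- reparametrize(path_curve(rbind(c(0, 0, 1), c(3, 4, 0)), P = 0))
  tg <- tangent(seg, c(0, 0.3, 1))
  expect_equal(tg, matrix(rep(c(3, 4, 0) / 5, each = 3), 3, 3),
               tolerance = 1e-10, ignore_attr = TRUE)
  # mirror-symmetric arch: at the apex the tangent is parallel to the
  # chord joining the endpoints (perpendicular to the bisecting radius);
  # exact for any curve whose x-component is antisymmetric and
  # y-component symmetric about the midpoint
  arch <- reparametrize(path_curve(rbind(c(3, 0), c(-6, 0), c(0, 3),
                                         c(0.9, 0)), P = 2))
  apex <- drop(tangent(arch, 0.5))
  expect_lt(abs(apex[2]), 1e-6)            # no radial component
  expect_equal(abs(apex[1]), 1, tolerance = 1e-6)
  # and a fitted semicircle shows the same symmetry within the fit residual
  tgrid <- seq(0, 1, length.out = 80)
  nodes <- cbind(3 * cos(pi * (1 - tgrid)), 3 * sin(pi * (1 - tgrid)))
  semi <- reparametrize(fit_curve(nodes, P = 3, tol = 1e-9, max_iter = 3000))
  expect_lt(abs(drop(tangent(semi, 0.5))[2]), 5e-3)
  # finite-difference oracle at 100 random parameters
  cv <- random_test_curve(d = 6, P = 1, seed = 13)
  set.seed(14)
  for (aa in runif(100, 0.01, 0.99)) {
    h <- 1e-6
    fd <- (path_eval(cv, aa + h) - path_eval(cv, aa - h)) / (2 * h)
    fd <- fd / sqrt(sum(fd^2))
    expect_equal(drop(tangent(cv, aa)), drop(fd), tolerance = 1e-5)
  }
  expect_equal(sqrt(rowSums(tangent(cv, seq(0, 1, 0.1))^2)),
               rep(1, 11), tolerance = 1e-10)
})

test_that("fit objective is non-increasing and endpoints stay consistent", {
  ends <- rbind(c(-2, 0), c(2, 0))
  ens <- make_synthetic_ensemble(ends[1, ], ends[2, ], n_frames = 1500,
                                 shape = "arc", bulge = 1, sigma = 0.15,
                                 seed = 6)
  nodes <- bin_and_average(ens, ends[1, ], ends[2, ], n_bins = 40)
  cv <- reparametrize(fit_curve(nodes, P = 1))
  # endpoint consistency within the fit residual scale
  res <- sqrt(cv$objective / nrow(nodes$nodes))
  expect_lt(sqrt(sum((drop(path_eval(cv, 0)) - nodes$nodes[1, ])^2)),
            10 * res + 0.05)
  expect_lt(sqrt(sum((drop(path_eval(cv, 1)) -
                        nodes$nodes[nrow(nodes$nodes), ])^2)), 10 * res + 0.05)
})
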