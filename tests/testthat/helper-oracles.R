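# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force minimization, dense grids, direct
# summation, binless reweighting.

# Rotation matrix from a (not necessarily unit) quaternion.
quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Brute-force minimum RMSD over all proper rotations (quaternion
# parametrization, multi-start BFGS), translations removed via centroids.
oracle_min_rmsd <- function(mobile, reference, n_starts = 12) {
  mm <- matrix(mobile, ncol = 3, byrow = TRUE)
  rr <- matrix(reference, ncol = 3, byrow = TRUE)
  mm <- sweep(mm, 2, colMeans(mm))
  rr <- sweep(rr, 2, colMeans(rr))
  obj <- function(q) {
    rot <- quat_rotation(q)
    sqrt(sum((mm %*% t(rot) - rr)^2) / nrow(mm))
  }
  best <- Inf
  set.seed(424242)
  for (s in seq_len(n_starts)) {
    q0 <- if (s == 1) c(1, 0, 0, 0) else rnorm(4)
    op <- optim(q0, obj, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-15))
    best <- min(best, op$value)
  }
  best
}

# Central finite-difference gradient.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Arc length of a curve by dense polyline summation.
oracle_polyline_length <- function(curve, n = 1e6) {
  tg <- seq(0, 1, length.out = n + 1)
  pts <- pathfe:::curve_point_t(curve, tg)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Geometric distance from points to a dense discretization of a reference
# path function (t -> matrix).
oracle_path_distance <- function(points, path_fun, n_dense = 20001) {
  dense <- path_fun(seq(0, 1, length.out = n_dense))
  vapply(seq_len(nrow(points)), function(i) {
    sqrt(min(rowSums(sweep(dense, 2, points[i, ])^2)))
  }, numeric(1))
}

# Binless multistate reweighting (MBAR-style self-consistent iteration):
# an independent estimator of the unbiased profile from harmonically
# biased 1D samples. Used only as a cross-check oracle.
oracle_mbar_profile <- function(samples_list, alpha_ref, kappa, kT,
                                edges, tol = 1e-10, max_iter = 5000) {
  n_i <- lengths(samples_list)
  x <- unlist(samples_list)
  s <- length(samples_list)
  # reduced bias of every pooled sample under every state
  u <- vapply(seq_len(s), function(i) {
    0.5 * kappa[i] * (x - alpha_ref[i])^2 / kT
  }, numeric(length(x)))            # N x S
  f <- numeric(s)
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(exp(sweep(-u, 2, f, `+`)) %*% n_i)  # sum_k N_k e^{f_k - u_k}
    f_new <- -log(colSums(exp(-u) / denom))
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  w <- 1 / as.numeric(exp(sweep(-u, 2, f, `+`)) %*% n_i)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  z <- vapply(seq_len(length(edges) - 1L),
              function(m) sum(w[idx == m]), numeric(1))
  fe <- -kT * log(z)
  fe - min(fe[is.finite(fe)])
}

# Exact biased double-well samples shared by the WHAM tests.
make_double_well_samples <- function(pot, alphas, kappa, n_per, kT = 1,
                                     seed = 100) {
  dplyr::bind_rows(lapply(seq_along(alphas), function(i) {
    biased <- function(x) pot$energy(x) + 0.5 * kappa * (x - alphas[i])^2
    s <- boltzmann_sample_1d(biased, n_per, range = c(-0.2, 1.2), kT = kT,
                             seed = seed + i)
    window_samples(i, alphas[i], kappa, s, cut = 0)
  }))
}

# Analytic bin-integrated free energy of a 1D potential on given centers.
oracle_marginal_profile <- function(pot, centers, width, kT = 1) {
  fe <- vapply(centers, function(c0) {
    -kT * log(integrate(function(x) exp(-vapply(x, pot$energy, numeric(1)) / kT),
                        c0 - width / 2, c0 + width / 2)$value)
  }, numeric(1))
  fe - min(fe)
}

# Random smooth test curve in D dimensions (reparametrized).
random_test_curve <- function(d = 4, P = 1, seed = 1, scale = 3) {
  set.seed(seed)
  coeffs <- rbind(rnorm(d), rnorm(d, sd = scale), matrix(rnorm(P * d), P, d))
  reparametrize(path_curve(coeffs, P = P))
}

expect_rms_lt <- function(x, bound) {
  expect_lt(sqrt(mean(x^2)), bound)
}
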