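#' Construct a toy potential
#'
#' A toy potential is an analytic energy surface with matching gradient,
#' used to validate the sampling and free-energy machinery without a
#' molecular-dynamics engine.
#'
#' @param energy function `x -> scalar` energy.
#' @param gradient function `x -> D-vector` gradient of `energy`.
#' @param dim dimensionality D.
#' @param params named list recording the construction parameters.
#' @return an object of class `"toy_potential"`.
#' @export
toy_potential <- function(energy, gradient, dim, params = list()) {
  structure(list(energy = energy, gradient = gradient, dim = as.integer(dim),
                 params = params),
            class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf("<toy_potential> D = %d (%s)\n", x$dim,
              paste(names(x$params), unlist(lapply(x$params, format)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Isotropic harmonic potential V = (k/2)|x - center|^2
#'
#' @param k spring constant; @param center minimum position.
#' @return a [toy_potential()].
#' @export
harmonic_potential <- function(k = 1, center = 0) {
  force(k); force(center)
  toy_potential(
    energy = function(x) 0.5 * k * sum((x - center)^2),
    gradient = function(x) k * (x - center),
    dim = length(center),
    params = list(kind = "harmonic", k = k)
  )
}

#' Quartic double-well potential in one dimension
#'
#' V(x) = h ((x - c)^2 - w^2)^2 / w^4 + tilt (x - c) / (2w): two minima at
#' c +/- w separated by a barrier of height h (at tilt = 0); `tilt` is
#' the energy difference between the two wells to first order.
#'
#' @param height barrier height h (energy units).
#' @param center barrier position c.
#' @param halfwidth well half-separation w.
#' @param tilt linear bias across the wells.
#' @return a [toy_potential()] with `dim = 1`.
#' @export
double_well_potential <- function(height = 3, center = 0.5, halfwidth = 0.25,
                                  tilt = 0) {
  force(height); force(center); force(halfwidth); force(tilt)
  toy_potential(
    energy = function(x) {
      u <- x[1] - center
      height * (u^2 - halfwidth^2)^2 / halfwidth^4 + tilt * u / (2 * halfwidth)
    },
    gradient = function(x) {
      u <- x[1] - center
      4 * height * u * (u^2 - halfwidth^2) / halfwidth^4 + tilt / (2 * halfwidth)
    },
    dim = 1L,
    params = list(kind = "double_well", height = height, center = center,
                  halfwidth = halfwidth, tilt = tilt)
  )
}

#' Curved-valley test potential
#'
#' A two-dimensional energy surface whose minimum-energy valley is a
#' circular arc of the given radius spanning polar angles [0, pi] in the
#' upper half-plane (endpoints on the x-axis at (+r, 0) and (-r, 0)):
#'
#'   V = (width_k/2) (r - radius)^2        harmonic valley wall
#'     + tilt * phi / pi                   linear tilt along the arc
#'     + (angle_k/2) (phi - angle0)^2      optional single-well trap
#'     + (wall_k/2) radius^2 dphi^2        soft walls beyond phi in [0, pi]
#'     + (width_k/2) sum z_extra^2         confinement of extra dimensions
#'
#' The polar angle phi uses a branch cut along the negative y-axis (far
#' from the valley), so the surface is smooth everywhere the valley floor
#' and walls are sampled. With `tilt = Delta` the two floor endpoints
#' differ in energy by exactly Delta; with `angle_k > 0` and `tilt = 0`
#' the floor has a single minimum at `angle0`.
#'
#' @param dim total dimensionality (>= 2); dimensions beyond the first two
#'   are harmonically confined at zero.
#' @param radius arc radius (> 0).
#' @param width_k valley wall stiffness (> 0).
#' @param tilt end-to-end energy difference along the arc.
#' @param angle_k single-well stiffness along the arc angle (0 disables).
#' @param angle0 angle of the single-well minimum (radians in [0, pi]).
#' @param wall_k stiffness of the soft end walls (defaults to `width_k`).
#' @return a [toy_potential()].
#' @export
curved_valley_potential <- function(dim = 2, radius = 3, width_k = 25,
                                    tilt = 0, angle_k = 0, angle0 = pi / 2,
                                    wall_k = width_k) {
  if (radius <= 0) abort("`radius` must be positive")
  if (width_k <= 0) abort("`width_k` must be positive")
  if (dim < 2) abort("`dim` must be at least 2")
  force(tilt); force(angle_k); force(angle0); force(wall_k)
  polar <- function(x) {
    r <- sqrt(x[[1]]^2 + x[[2]]^2)
    phi <- atan2(x[[2]], x[[1]])
    if (phi < -pi / 2) phi <- phi + 2 * pi    # branch cut along -y axis
    c(r = r, phi = phi)
  }
  energy <- function(x) {
    p <- polar(x)
    dphi <- if (p["phi"] < 0) p["phi"] else if (p["phi"] > pi) p["phi"] - pi else 0
    e <- 0.5 * width_k * (p["r"] - radius)^2 +
      tilt * p["phi"] / pi +
      0.5 * angle_k * (p["phi"] - angle0)^2 +
      0.5 * wall_k * radius^2 * dphi^2
    if (length(x) > 2L) e <- e + 0.5 * width_k * sum(x[-(1:2)]^2)
    unname(e)
  }
  gradient <- function(x) {
    p <- polar(x)
    r <- p[["r"]]; phi <- p[["phi"]]
    if (r < 1e-12) abort("gradient undefined at the arc center")
    dphi <- if (phi < 0) phi else if (phi > pi) phi - pi else 0
    dV_dr <- width_k * (r - radius)
    dV_dphi <- tilt / pi + angle_k * (phi - angle0) + wall_k * radius^2 * dphi
    # dr/dx = x/r, dr/dy = y/r; dphi/dx = -y/r^2, dphi/dy = x/r^2
    g <- c(dV_dr * x[1] / r - dV_dphi * x[2] / r^2,
           dV_dr * x[2] / r + dV_dphi * x[1] / r^2)
    if (length(x) > 2L) g <- c(g, width_k * x[-(1:2)])
    g
  }
  toy_potential(energy, gradient, dim,
                params = list(kind = "curved_valley", radius = radius,
                              width_k = width_k, tilt = tilt,
                              angle_k = angle_k, angle0 = angle0,
                              wall_k = wall_k))
}

#' Arc-floor point of a curved-valley potential
#'
#' The valley-floor point at fraction `t` along the arc (t = 0 at angle
#' pi, the (-r, 0) end; t = 1 at angle 0), handy for building endpoint
#' and initial configurations on the floor.
#'
#' @param pot a curved-valley [toy_potential()].
#' @param t fraction(s) along the arc in [0, 1].
#' @return length(t)-by-dim matrix of floor points.
#' @export
valley_floor <- function(pot, t) {
  stopifnot(identical(pot$params$kind, "curved_valley"))
  r <- pot$params$radius
  th <- pi * (1 - t)
  cbind(r * cos(th), r * sin(th),
        matrix(0, length(t), pot$dim - 2L))
}

#' Overdamped Langevin sampler
#'
#' Euler-Maruyama integration of overdamped Langevin dynamics:
#' x <- x - (dt/gamma) grad V(x) + sqrt(2 kT dt / gamma) xi, with
#' standard-normal xi drawn from the seeded stream. Only equilibrium
#' sampling matters for the free-energy machinery, so no inertial terms
#' are included.
#'
#' @param pot a [toy_potential()].
#' @param x0 initial configuration (length `pot$dim`).
#' @param dt time step (> 0).
#' @param gamma friction coefficient (> 0).
#' @param kT thermal energy (>= 0; 0 gives deterministic steepest descent).
#' @param n_steps number of steps.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param extra_bias optional restraint: a list with `energy` and
#'   `gradient` functions added to the potential (e.g. an umbrella bias).
#' @return an `(n_steps + 1)`-by-D matrix of states, first row `x0`.
#' @export
run_langevin <- function(pot, x0, dt, gamma = 1, kT = 1, n_steps = 1000,
                         seed = NULL, extra_bias = NULL) {
  if (dt <= 0 || gamma <= 0) abort("`dt` and `gamma` must be positive")
  if (kT < 0) abort("`kT` must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483587))
  d <- length(x0)
  x <- as.numeric(x0)
  out <- matrix(NA_real_, n_steps + 1L, d)
  out[1L, ] <- x
  a <- dt / gamma
  noise_amp <- sqrt(2 * kT * dt / gamma)
  for (s in seq_len(n_steps)) {
    g <- pot$gradient(x)
    if (!is.null(extra_bias)) g <- g + extra_bias$gradient(x)
    x <- x - a * g
    if (noise_amp > 0) x <- x + noise_amp * rnorm(d)
    if (!all(is.finite(x))) {
      abort(sprintf("Langevin trajectory diverged at step %d", s))
    }
    out[s + 1L, ] <- x
  }
  out
}

#' Langevin propagator for replica exchange
#'
#' Wraps [run_langevin()] into the `(x, bias, seed)` closure that
#' [run_hrex()] expects; each call advances `steps_per_cycle` steps under
#' `pot` plus the window bias and returns the final state.
#'
#' @inheritParams run_langevin
#' @param steps_per_cycle Langevin steps per exchange interval.
#' @param windows an `"umbrella_windows"` table: the window biases.
#' @return list with `propagate`, `biases` (window energy functions) and
#'   `record` (the linearized window projection [window_alpha()]), ready
#'   to pass to [run_hrex()].
#' @export
langevin_hrex_setup <- function(pot, windows, dt, gamma = 1, kT = 1,
                                steps_per_cycle = 10) {
  ww <- lapply(seq_len(nrow(windows)), function(i) window_at(windows, i))
  # lean closures: these run in the Langevin inner loop
  biases <- lapply(ww, function(w) {
    anc <- w$anchor; tg <- w$tangent; K <- w$K
    function(x) 0.5 * K * sum((x - anc) * tg)^2
  })
  bias_grads <- lapply(ww, function(w) {
    anc <- w$anchor; tg <- w$tangent; K <- w$K
    function(x) K * sum((x - anc) * tg) * tg
  })
  propagate <- function(x, bias, seed) {
    i <- attr(bias, "window_index")
    eb <- list(energy = bias, gradient = bias_grads[[i]])
    traj <- run_langevin(pot, x, dt = dt, gamma = gamma, kT = kT,
                         n_steps = steps_per_cycle, seed = seed,
                         extra_bias = eb)
    traj[nrow(traj), ]
  }
  for (i in seq_along(biases)) attr(biases[[i]], "window_index") <- i
  record <- function(x, window) window_alpha(ww[[window]], x)
  list(propagate = propagate, biases = biases, record = record)
}

#' Generate a synthetic conformational ensemble around a known path
#'
#' Emulates the scatter of unrestrained-trajectory frames around a
#' transition pathway: frames are placed at uniform path parameters along
#' a known curve between two endpoint conformations and perturbed by
#' i.i.d. Gaussian coordinate noise. The generating path is retained so
#' tests can assert recovery.
#'
#' Path shapes: `"line"` (straight segment), `"arc"` (the chord plus a
#' perpendicular sine bulge of height `bulge` — a curved path exactly
#' representable by the P = 1 sinusoidal curve basis), `"semicircle"`
#' (a true half-circle in the plane of the chord and the bulge
#' direction).
#'
#' @param a,b endpoint conformations (equal length D).
#' @param n_frames number of frames.
#' @param shape `"line"`, `"arc"`, or `"semicircle"`.
#' @param bulge perpendicular bulge height for `"arc"` (Å; default 15%
#'   of the chord length).
#' @param sigma per-coordinate Gaussian noise standard deviation (Å).
#' @param seed integer seed.
#' @param dt frame spacing passed to the ensemble (ps).
#' @return an [ensemble()] with attributes `true_path` (function
#'   `t -> matrix`) and `path_t` (the frame path parameters).
#' @export
make_synthetic_ensemble <- function(a, b, n_frames = 1000,
                                    shape = c("arc", "line", "semicircle"),
                                    bulge = NULL, sigma = 0.5, seed = 1,
                                    dt = NULL) {
  shape <- match.arg(shape)
  a <- as_coords(a); b <- as_coords(b)
  check_same_dim(a, b, "endpoints")
  if (sigma < 0) abort("`sigma` must be non-negative")
  if (n_frames < 1) abort("`n_frames` must be at least 1")
  chord <- b - a
  clen <- sqrt(sum(chord^2))
  if (clen < 1e-12) abort("endpoints coincide")
  u <- chord / clen
  perp <- perp_direction(u)
  if (is.null(bulge)) bulge <- 0.15 * clen
  path_fun <- switch(shape,
    line = function(t) outer(t, chord) + rep(a, each = length(t)),
    arc = function(t) {
      outer(t, chord) + rep(a, each = length(t)) +
        outer(bulge * sin(pi * t), perp)
    },
    semicircle = function(t) {
      ctr <- (a + b) / 2
      r <- clen / 2
      th <- pi * (1 - t)
      outer(r * cos(th), u) + outer(r * sin(th), perp) +
        rep(ctr, each = length(t))
    }
  )
  set.seed(as.integer(seed %% 2147483587))
  tt <- if (n_frames == 1L) 0.5 else seq(0, 1, length.out = n_frames)
  frames <- path_fun(tt)
  if (sigma > 0) {
    frames <- frames + matrix(rnorm(length(frames), sd = sigma),
                              nrow = nrow(frames))
  }
  ens <- ensemble(frames, dt = dt)
  attr(ens, "true_path") <- path_fun
  attr(ens, "path_t") <- tt
  ens
}

# Deterministic unit vector orthogonal to u: Gram-Schmidt of the first
# coordinate axis not parallel to u.
perp_direction <- function(u) {
  d <- length(u)
  for (j in seq_len(d)) {
    e <- numeric(d); e[j] <- 1
    v <- e - sum(e * u) * u
    if (sqrt(sum(v^2)) > 1e-6) return(v / sqrt(sum(v^2)))
  }
  abort("could not construct a perpendicular direction")
}

#' Brute-force free energy along a curve (quadrature oracle)
#'
#' Computes F(alpha) = -kT log integral of exp(-V/kT) over the set of
#' configurations whose curve projection falls in each alpha bin, on a
#' dense spatial grid (dims <= 3) or by Monte-Carlo integration in a
#' bounding box (higher dims). This is the independent ground truth the
#' sampled (HREX + WHAM) profile is compared against.
#'
#' @param pot a [toy_potential()].
#' @param curve a reparametrized `"path_curve"` with `curve$dim ==
#'   pot$dim`.
#' @param alpha_bins number of equal alpha bins on [0, 1].
#' @param kT thermal energy.
#' @param grid_n grid points per spatial dimension (dense quadrature).
#' @param padding box padding beyond the curve's bounding box, in units
#'   of the thermal width sqrt(kT / k_min) estimated from the potential
#'   at the curve ends, plus this absolute amount.
#' @param mc_samples Monte-Carlo sample count for dims > 3.
#' @param check if `TRUE`, recompute at half resolution and error out
#'   when the RMS difference exceeds `check_tol` (kT).
#' @param check_tol discretization tolerance in kT for `check`.
#' @param seed seed for the Monte-Carlo branch.
#' @return a `"fep"` tibble (alpha, free_energy, std_error = NA) with
#'   attribute `resolution` describing the quadrature.
#' @export
reference_free_energy <- function(pot, curve, alpha_bins = 60, kT = 1,
                                  grid_n = 240, padding = 1.5,
                                  mc_samples = 2e5, check = FALSE,
                                  check_tol = 0.02, seed = 1) {
  if (pot$dim != curve$dim) abort("potential and curve dimensions differ")
  compute <- function(gn) {
    box <- curve_bounding_box(curve, padding)
    if (pot$dim <= 3) {
      axes <- lapply(seq_len(pot$dim), function(j) {
        seq(box[1, j], box[2, j], length.out = gn)
      })
      grid <- as.matrix(expand.grid(axes))
      cell <- prod(vapply(axes, function(a) a[2] - a[1], numeric(1)))
      v <- apply(grid, 1L, pot$energy)
      w <- exp(-(v - min(v)) / kT) * cell
      keep <- w > max(w) * 1e-14
      grid <- grid[keep, , drop = FALSE]
      w <- w[keep]
    } else {
      set.seed(as.integer(seed %% 2147483587))
      grid <- vapply(seq_len(pot$dim), function(j) {
        runif(mc_samples, box[1, j], box[2, j])
      }, numeric(mc_samples))
      vol <- prod(box[2, ] - box[1, ])
      v <- apply(grid, 1L, pot$energy)
      w <- exp(-(v - min(v)) / kT) * vol / mc_samples
    }
    al <- project_nearest(curve, grid)
    hb <- 1 / alpha_bins
    centers <- (seq_len(alpha_bins) - 0.5) * hb
    # cloud-in-cell deposition: each point's weight is split linearly
    # between the two nearest bin centers, suppressing grid aliasing
    g <- al / hb - 0.5
    i0 <- floor(g)
    frac <- g - i0
    i0 <- i0 + 1L
    z <- numeric(alpha_bins)
    ok0 <- i0 >= 1L & i0 <= alpha_bins
    ok1 <- i0 + 1L >= 1L & i0 + 1L <= alpha_bins
    z_lo <- tapply(w[ok0] * (1 - frac[ok0]), i0[ok0], sum)
    z_hi <- tapply(w[ok1] * frac[ok1], i0[ok1] + 1L, sum)
    z[as.integer(names(z_lo))] <- z[as.integer(names(z_lo))] + z_lo
    z[as.integer(names(z_hi))] <- z[as.integer(names(z_hi))] + z_hi
    fe <- -kT * log(z)
    fe <- fe - min(fe[is.finite(fe)])
    list(centers = centers, fe = fe)
  }
  full <- compute(grid_n)
  if (check) {
    half <- compute(max(20L, grid_n %/% 2L))
    ok <- is.finite(full$fe) & is.finite(half$fe)
    disc <- sqrt(mean((full$fe[ok] - half$fe[ok])^2))
    if (disc > check_tol * kT) {
      abort(sprintf("quadrature grid too coarse: half-resolution RMS change %.3g kT",
                    disc / kT))
    }
  }
  out <- tibble(alpha = full$centers, free_energy = full$fe,
                std_error = NA_real_)
  structure(out, kT = kT, iterations = NA_integer_, converged = NA,
            f_windows = numeric(0), n_samples = NA_integer_,
            resolution = if (pot$dim <= 3) sprintf("grid %d^%d", grid_n, pot$dim)
                         else sprintf("MC %g samples", mc_samples),
            class = c("fep", class(out)))
}

curve_bounding_box <- function(curve, padding) {
  pts <- path_eval(curve, seq(0, 1, length.out = 201))
  lo <- apply(pts, 2L, min) - padding
  hi <- apply(pts, 2L, max) + padding
  rbind(lo, hi)
}

# Nearest-point projection of many points via a dense alpha discretization
# (vectorized, chunked to bound memory); the quadrature oracle's workhorse.
project_nearest <- function(curve, x, n_dense = 2001L, chunk = 2000L) {
  ag <- seq(0, 1, length.out = n_dense)
  pts <- path_eval(curve, ag)
  p2 <- rowSums(pts^2)
  n <- nrow(x)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    xc <- x[idx, , drop = FALSE]
    # squared distance up to a per-point constant
    d2 <- matrix(p2, length(idx), n_dense, byrow = TRUE) -
      2 * xc %*% t(pts)
    out[idx] <- ag[max.col(-d2, ties.method = "first")]
  }
  out
}

#' Draw Boltzmann-distributed samples from a 1D potential
#'
#' Inverse-CDF sampling of p(x) proportional to exp(-(V(x) + bias)/kT) on
#' a fine grid with linear interpolation inside cells; with the default
#' grid the discretization is far below any histogram resolution used
#' downstream, so the draws serve as exact-reference Boltzmann samples
#' for validating estimators.
#'
#' @param energy function `x -> scalar` (vectorization not required).
#' @param n number of samples.
#' @param range length-2 support interval.
#' @param kT thermal energy.
#' @param seed integer seed; `NULL` continues the current stream.
#' @param grid_n grid resolution for the CDF.
#' @return numeric vector of n samples.
#' @export
boltzmann_sample_1d <- function(energy, n, range = c(0, 1), kT = 1,
                                seed = NULL, grid_n = 32768L) {
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483587))
  xg <- seq(range[1], range[2], length.out = grid_n)
  v <- vapply(xg, energy, numeric(1))
  w <- exp(-(v - min(v)) / kT)
  cdf <- cumsum(w)
  cdf <- cdf / cdf[grid_n]
  u <- runif(n)
  idx <- findInterval(u, cdf) + 1L
  idx <- pmin(pmax(idx, 2L), grid_n)
  lo <- cdf[idx - 1L]
  hi <- cdf[idx]
  frac <- ifelse(hi > lo, (u - lo) / (hi - lo), 0.5)
  xg[idx - 1L] + frac * (xg[idx] - xg[idx - 1L])
}

#' Desk-scale free-energy study on the curved-valley toy
#'
#' Runs the complete pipeline on a two-dimensional curved-valley system:
#' synthetic ensemble around the valley, principal-curve construction
#' (bin averaging, sinusoidal fit, arc-length reparametrization), 30
#' tangent-restrained umbrella windows, Hamiltonian replica exchange with
#' overdamped Langevin sampling, and WHAM reconstruction with error
#' propagation. The `"tilted"` variant imposes a 4 kT end-to-end
#' free-energy difference along the valley; the `"single_well"` variant
#' traps the arc angle in one basin so the reconstructed profile has a
#' single minimum.
#'
#' Study conditions (see the methods vignette for the reasoning): valley
#' radius 3, wall stiffness 25 (kT units, perpendicular thermal width
#' 0.2); ensemble of 4,000 frames with 0.2 coordinate noise; 100
#' projection bins; P = 2 sine modes (the semicircular valley bends too
#' tightly for a single mode); 30 windows with K = 5 (strongly
#' overlapping, sigma_alpha about 1.5 window spacings); Langevin dt =
#' 0.003, 25 steps per exchange attempt; first quarter of each window
#' discarded as equilibration.
#'
#' @param kind `"tilted"` (4 kT end-to-end tilt) or `"single_well"`.
#' @param seed integer seed driving every random stage.
#' @param n_cycles exchange cycles (default 8000 tilted, 2500 single-well).
#' @param with_reference also compute the quadrature-oracle profile.
#' @return list with `potential`, `ensemble`, `curve`, `windows`, `run`
#'   (the `"hrex_run"`), `samples`, `profile` (WHAM `"fep"` with errors),
#'   `reference` (oracle `"fep"` or `NULL`), and `endpoints_alpha` (the
#'   projections of the two valley-floor endpoints).
#' @export
toy_free_energy_study <- function(kind = c("tilted", "single_well"),
                                  seed = 1, n_cycles = NULL,
                                  with_reference = TRUE) {
  kind <- match.arg(kind)
  kT <- 1
  pot <- switch(kind,
    tilted = curved_valley_potential(radius = 3, width_k = 25, tilt = 4),
    single_well = curved_valley_potential(radius = 3, width_k = 25,
                                          tilt = 0, angle_k = 1.5)
  )
  if (is.null(n_cycles)) n_cycles <- if (kind == "tilted") 8000 else 2500
  ends <- valley_floor(pot, c(0, 1))
  ens <- make_synthetic_ensemble(ends[1, ], ends[2, ], n_frames = 4000,
                                 shape = "semicircle", sigma = 0.2,
                                 seed = seed + 1000)
  nodes <- bin_and_average(ens, ends[1, ], ends[2, ], n_bins = 100)
  curve <- reparametrize(fit_curve(nodes, P = 2, tol = 1e-9, max_iter = 2000))
  windows <- window_layout(curve, n_windows = 30, K = 5)
  setup <- langevin_hrex_setup(pot, windows, dt = 0.003, gamma = 1, kT = kT,
                               steps_per_cycle = 25)
  x0 <- lapply(windows$alpha, function(a) drop(path_eval(curve, a)))
  run <- run_hrex(setup$propagate, x0, setup$biases, n_cycles = n_cycles,
                  kT = kT, record = setup$record, seed = seed)
  samples <- collect_samples(run, windows, cut = 0.25)
  profile <- wham_error(samples, wham_1d(samples, n_bins = 120, kT = kT))
  reference <- if (with_reference) {
    reference_free_energy(pot, curve, alpha_bins = 120, kT = kT, grid_n = 300)
  }
  list(potential = pot, ensemble = ens, curve = curve, windows = windows,
       run = run, samples = samples, profile = profile,
       reference = reference, endpoints_alpha = project(curve, ends),
       kT = kT)
}

#' Compare two free-energy profiles over an alpha range
#'
#' Interpolates `reference` onto `profile`'s grid, restricts to the given
#' range, removes the additive gauge (profiles are defined up to a
#' constant) by mean alignment, and reports the RMS difference.
#'
#' @param profile,reference `"fep"` objects.
#' @param range alpha interval compared.
#' @return list with `rms`, `n` (bins compared) and `residual`.
#' @export
profile_rms <- function(profile, reference, range = c(0.05, 0.95)) {
  ok <- profile$alpha >= range[1] & profile$alpha <= range[2]
  fr <- approx(reference$alpha, reference$free_energy,
               xout = profile$alpha[ok], rule = 2)$y
  r <- profile$free_energy[ok] - fr
  r <- r - mean(r)
  list(rms = sqrt(mean(r^2)), n = sum(ok), residual = r)
}
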