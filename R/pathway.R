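#' Project a conformation onto the straight line between two endpoints
#'
#' Returns the scalar line coordinate lambda such that `a + lambda*(b - a)`
#' is the orthogonal projection of `x` onto the line through `a` and `b`:
#' lambda = (x - a).(b - a) / |b - a|^2. Values outside [0, 1] indicate
#' points beyond the endpoints and are returned as-is.
#'
#' @param x a conformation (D-vector) or a frames-by-D matrix.
#' @param a,b the two endpoint conformations; must differ.
#' @return numeric lambda, one value per row of `x`.
#' @examples
#' line_project(c(0.5, 1), c(0, 0), c(1, 0))
#' @export
line_project <- function(x, a, b) {
  a <- as_coords(a); b <- as_coords(b)
  check_same_dim(a, b, "endpoints")
  ab <- b - a
  n2 <- sum(ab^2)
  if (n2 < 1e-24) abort("degenerate line: the two endpoints coincide")
  if (is.matrix(x)) {
    if (ncol(x) != length(a)) abort("frame dimension does not match endpoints")
    as.numeric(sweep(unclass(x), 2L, a) %*% ab) / n2
  } else {
    x <- as_coords(x)
    check_same_dim(x, a)
    sum((x - a) * ab) / n2
  }
}

#' Bin trajectory frames along the endpoint line and average each bin
#'
#' Every frame (optionally Kabsch-aligned to `reference` first) is
#' projected onto the straight line between `a` and `b`; the observed
#' projection range is divided into `n_bins` equal segments; and the
#' component-wise mean coordinate of the frames in each segment is
#' returned, ordered by segment. These bin averages delineate the center
#' of the conformational region the trajectories visited, and are the
#' nodes through which [fit_curve()] draws the smooth pathway. Bins that
#' receive no frames are dropped.
#'
#' @param ensembles an [ensemble()] or list of ensembles (equal D).
#' @param a,b endpoint conformations defining the projection line.
#' @param n_bins number of equal segments over the covered range.
#' @param reference conformation for rigid-body alignment of every frame,
#'   or `NULL` to skip alignment (toy systems, pre-aligned input).
#' @return an object of class `"path_nodes"`: list with `nodes` (K-by-D
#'   matrix), `counts`, `lambda` (bin-center line coordinates) and
#'   `range` (the covered lambda range).
#' @export
bin_and_average <- function(ensembles, a, b, n_bins = 100, reference = NULL) {
  if (!is.list(ensembles) || is.matrix(ensembles)) ensembles <- list(ensembles)
  frames <- do.call(rbind, lapply(ensembles, frame_matrix))
  if (nrow(frames) < 1L) abort("no frames supplied")
  if (n_bins < 2L) abort("`n_bins` must be at least 2")
  if (!is.null(reference)) frames <- align_frames(frames, reference)
  lam <- line_project(frames, a, b)
  rng <- range(lam)
  if (diff(rng) < 1e-12) abort("zero projection range: all frames project identically")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(lam, edges, rightmost.closed = TRUE, all.inside = TRUE)
  keep <- sort(unique(idx))
  nodes <- do.call(rbind, lapply(keep, function(k) {
    colMeans(frames[idx == k, , drop = FALSE])
  }))
  structure(
    list(nodes = nodes,
         counts = as.integer(tabulate(idx, n_bins)[keep]),
         lambda = (edges[keep] + edges[keep + 1L]) / 2,
         range = rng),
    class = "path_nodes"
  )
}

#' @export
print.path_nodes <- function(x, ...) {
  cat(sprintf("<path_nodes> %d node(s), D = %d, lambda range [%.3f, %.3f]\n",
              nrow(x$nodes), ncol(x$nodes), x$range[1], x$range[2]))
  invisible(x)
}

#' @method as_tibble path_nodes
#' @export
as_tibble.path_nodes <- function(x, ...) {
  tibble(node = seq_along(x$counts), lambda = x$lambda, count = x$counts,
         coords = lapply(seq_len(nrow(x$nodes)), function(i) x$nodes[i, ]))
}

# --- sinusoidal curve basis -------------------------------------------------
# Per dimension: f(t) = a + b t + sum_{p=1..P} c_p sin(p pi t), t in [0,1].
# Infinitely differentiable, hence suitable for the tangent-linearization
# used by the umbrella restraints.

basis_matrix <- function(t, P) {
  out <- cbind(1, t)
  for (p in seq_len(P)) out <- cbind(out, sin(p * pi * t))
  out
}

dbasis_matrix <- function(t, P) {
  out <- cbind(0 * t, 1 + 0 * t)
  for (p in seq_len(P)) out <- cbind(out, p * pi * cos(p * pi * t))
  out
}

#' Construct a path curve from basis coefficients
#'
#' Builds a `"path_curve"` directly from a coefficient matrix — one row
#' per basis function (constant, linear, then the P sine modes), one
#' column per dimension. Mainly useful for constructing analytic test
#' curves; [fit_curve()] is the data-driven constructor.
#'
#' @param coeffs a (2 + P)-by-D numeric matrix.
#' @param P number of sine modes (`nrow(coeffs) - 2`).
#' @return a `"path_curve"` in internal parametrization.
#' @examples
#' seg <- path_curve(rbind(c(0, 0), c(1, 2)), P = 0)   # straight segment
#' arc_length(seg, 1)
#' @export
path_curve <- function(coeffs, P = nrow(coeffs) - 2L) {
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) != P + 2L) abort("`coeffs` must have P + 2 rows")
  new_path_curve(coeffs, P)
}

new_path_curve <- function(coeffs, P, t_nodes = NULL, objective = NA_real_,
                           iterations = NA_integer_, converged = NA) {
  cv <- structure(
    list(dim = ncol(coeffs), P = P, coeffs = coeffs, t_nodes = t_nodes,
         objective = objective, iterations = iterations, converged = converged,
         uniform = FALSE, arc = NULL, L = NA_real_),
    class = "path_curve"
  )
  cv$arc <- arc_table(cv, n = 2001L)
  cv$L <- cv$arc$s[length(cv$arc$s)]
  cv
}

# Raw-parameter evaluation and derivative (internal t, not alpha).
curve_point_t <- function(curve, t) basis_matrix(t, curve$P) %*% curve$coeffs
curve_deriv_t <- function(curve, t) dbasis_matrix(t, curve$P) %*% curve$coeffs
curve_speed_t <- function(curve, t) sqrt(rowSums(curve_deriv_t(curve, t)^2))

# Cumulative arc length on a uniform t grid, composite Simpson per cell.
arc_table <- function(curve, n = 2001L) {
  tg <- seq(0, 1, length.out = n)
  h <- tg[2] - tg[1]
  f <- curve_speed_t(curve, tg)
  fm <- curve_speed_t(curve, tg[-n] + h / 2)
  inc <- (h / 6) * (f[-n] + 4 * fm + f[-1])
  list(t = tg, s = c(0, cumsum(inc)))
}

#' Fit a smooth sinusoidal curve through path nodes
#'
#' Fits, per dimension i, f_i(t) = a_i + b_i t + sum_p c_ip sin(p pi t)
#' by minimizing the total squared distance between the curve and the
#' nodes, jointly over the basis coefficients and the per-node parameters
#' t_k. The optimization alternates exact linear least squares for the
#' coefficients (given t_k) with bounded one-dimensional minimization of
#' each interior t_k (given coefficients); the first and last nodes are
#' pinned to t = 0 and t = 1. The objective is non-increasing across
#' iterations by construction.
#'
#' @param nodes a `"path_nodes"` object from [bin_and_average()], or a
#'   K-by-D matrix of ordered node coordinates.
#' @param P number of sine modes per dimension (P = 1 keeps curvature
#'   small; larger P follows tighter bends).
#' @param tol relative objective-improvement tolerance for convergence.
#' @param max_iter maximum alternating iterations.
#' @return a `"path_curve"` in its internal parametrization (call
#'   [reparametrize()] before laying out windows).
#' @export
fit_curve <- function(nodes, P = 1, tol = 1e-10, max_iter = 500) {
  if (inherits(nodes, "path_nodes")) nodes <- nodes$nodes
  nodes <- as.matrix(nodes)
  if (P < 0) abort("`P` must be non-negative")
  k <- nrow(nodes)
  if (k < P + 2) abort(sprintf("need at least P + 2 = %d nodes, got %d", P + 2, k))
  tk <- seq(0, 1, length.out = k)  # init: proportional to node order
  obj_of <- function(coeffs, tk) sum((basis_matrix(tk, P) %*% coeffs - nodes)^2)
  coeffs <- NULL
  obj <- Inf
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    x <- basis_matrix(tk, P)
    coeffs <- qr.solve(x, nodes)            # LS for all D dims at once
    node_dist2 <- function(t, k_) sum((drop(basis_matrix(t, P) %*% coeffs) - nodes[k_, ])^2)
    if (k > 2) {
      for (k_ in 2:(k - 1)) {
        op <- optimize(node_dist2, c(0, 1), k_ = k_, tol = 1e-12)
        if (op$objective < node_dist2(tk[k_], k_)) tk[k_] <- op$minimum
      }
    }
    new_obj <- obj_of(coeffs, tk)
    if (is.finite(obj) && (obj - new_obj) <= tol * max(obj, 1e-300)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
    if (iter >= max_iter) break
  }
  if (!converged) {
    abort(sprintf("curve fit did not converge in %d iterations (objective %.6g)",
                  max_iter, obj))
  }
  # keep node parameters ordered; ties broken by original order
  ord <- order(tk)
  new_path_curve(coeffs, P, t_nodes = tk[ord], objective = obj,
                 iterations = iter, converged = TRUE)
}

#' Arc length along a path curve
#'
#' s(t) = integral from 0 to t of |dZ/dt'| dt', by adaptive quadrature on
#' the analytic speed. `arc_length(curve, 1)` is the total length L.
#'
#' @param curve a `"path_curve"`.
#' @param t parameter value(s) in [0, 1] (the curve's own parameter:
#'   internal t for a raw fit, alpha for a reparametrized curve).
#' @return arc length(s), same units as the coordinates (Å).
#' @export
arc_length <- function(curve, t) {
  if (any(t < 0 | t > 1)) abort("`t` must lie in [0, 1]")
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    tt <- if (isTRUE(curve$uniform)) t_of_alpha(curve, ti) else ti
    integrate(function(u) curve_speed_t(curve, u), 0, tt,
              rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 400L)$value
  }, numeric(1))
}

# Monotone (Hyman-filtered) spline inverting s(t) = alpha * L.
t_of_alpha <- function(curve, alpha) {
  tab <- curve$arc
  if (any(diff(tab$s) <= 0)) abort("arc-length table is not strictly increasing")
  f <- splinefun(tab$s / curve$L, tab$t, method = "hyman")
  pmin(1, pmax(0, f(alpha)))
}

#' Reparametrize a fitted curve by arc length
#'
#' Returns the same geometric curve re-indexed by the normalized arc
#' length alpha in [0, 1]: Z(alpha) = Z_old(t(alpha)) where t inverts
#' s(t) = alpha * L. After reparametrization the speed |dZ/dalpha| equals
#' L uniformly, so equal steps in alpha are equal steps along the pathway
#' — the property the tangent-restraint linearization relies on. The
#' inversion uses monotone cubic interpolation of a dense arc-length
#' table.
#'
#' @param curve a `"path_curve"` from [fit_curve()].
#' @return the curve with uniform (constant-speed) parametrization.
#' @export
reparametrize <- function(curve) {
  if (any(diff(curve$arc$s) <= 0)) abort("arc-length table is not strictly increasing")
  curve$uniform <- TRUE
  curve
}

#' Evaluate a path curve
#'
#' @param curve a `"path_curve"`.
#' @param alpha parameter value(s) in [0, 1]; interpreted as the uniform
#'   arc-length parameter for a reparametrized curve, or as the internal
#'   fit parameter otherwise.
#' @return a length(alpha)-by-D matrix of curve points.
#' @export
path_eval <- function(curve, alpha) {
  if (any(alpha < -1e-12 | alpha > 1 + 1e-12)) abort("`alpha` must lie in [0, 1]")
  alpha <- pmin(1, pmax(0, alpha))
  tt <- if (isTRUE(curve$uniform)) t_of_alpha(curve, alpha) else alpha
  curve_point_t(curve, tt)
}

#' Unit tangent of a reparametrized curve
#'
#' e(alpha) = (dZ/dalpha) / |dZ/dalpha|, evaluated analytically from the
#' basis derivative. For a constant-speed curve |dZ/dalpha| = L, so the
#' tangent is the derivative scaled by 1/L.
#'
#' @param curve a reparametrized `"path_curve"`.
#' @param alpha parameter value(s) in [0, 1].
#' @return a length(alpha)-by-D matrix of unit tangent vectors.
#' @export
tangent <- function(curve, alpha) {
  if (!isTRUE(curve$uniform)) {
    abort("tangent() expects a reparametrized (constant-speed) curve")
  }
  if (any(alpha < 0 | alpha > 1)) abort("`alpha` must lie in [0, 1]")
  tt <- t_of_alpha(curve, alpha)
  d <- curve_deriv_t(curve, tt)
  sp <- sqrt(rowSums(d^2))
  if (any(sp < 1e-14)) abort("zero curve derivative: tangent undefined")
  d / sp
}

#' @export
print.path_curve <- function(x, ...) {
  cat(sprintf("<path_curve> D = %d, P = %d, L = %.4f, %s parametrization\n",
              x$dim, x$P, x$L,
              if (isTRUE(x$uniform)) "uniform (arc-length)" else "internal"))
  if (!is.na(x$objective)) {
    cat(sprintf("  fit objective %.6g after %d iteration(s)\n", x$objective, x$iterations))
  }
  invisible(x)
}

#' @method tidy path_curve
#' @export
tidy.path_curve <- function(x, ...) {
  cf <- x$coeffs
  nm <- c("intercept", "linear", paste0("sine", seq_len(x$P)))
  tibble(
    dimension = rep(seq_len(x$dim), each = nrow(cf)),
    term = rep(nm, times = x$dim),
    estimate = as.numeric(cf)
  )
}

#' @method glance path_curve
#' @export
glance.path_curve <- function(x, ...) {
  tibble(dim = x$dim, P = x$P, L = x$L, objective = x$objective,
         iterations = x$iterations, converged = isTRUE(x$converged),
         uniform = isTRUE(x$uniform))
}
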