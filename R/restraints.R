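#' Project a conformation onto the curve (closest point)
#'
#' The projection operator maps a conformation x to the curve parameter
#' alpha* of the curve point nearest to x. The global minimum of
#' |x - Z(alpha)| over [0, 1] is located by a coarse grid scan followed by
#' bounded local refinement; points beyond either end of the curve are
#' clamped to the boundary value. This nonlinear projection is used for
#' analysis and reporting; the umbrella forces use the per-window linear
#' (tangent) projection instead.
#'
#' @param curve a reparametrized `"path_curve"`.
#' @param x a conformation (D-vector) or frames-by-D matrix.
#' @param n_grid number of coarse-scan points (>= 201 recommended).
#' @return alpha* in [0, 1], one value per row of `x`.
#' @export
project <- function(curve, x, n_grid = 201L) {
  xm <- if (is.matrix(x)) unclass(x) else matrix(as_coords(x), nrow = 1L)
  if (ncol(xm) != curve$dim) abort("conformation dimension does not match the curve")
  ag <- seq(0, 1, length.out = n_grid)
  pts <- path_eval(curve, ag)
  p2 <- rowSums(pts^2)
  vapply(seq_len(nrow(xm)), function(i) {
    xi <- xm[i, ]
    d2 <- p2 - 2 * as.numeric(pts %*% xi)   # |x|^2 constant: omit
    k <- which.min(d2)
    lo <- ag[max(1L, k - 1L)]
    hi <- ag[min(n_grid, k + 1L)]
    f <- function(a) sum((drop(path_eval(curve, a)) - xi)^2)
    op <- optimize(f, c(lo, hi), tol = 1e-10)
    cand <- c(op$minimum, lo, hi)
    cand[which.min(vapply(cand, f, numeric(1)))]
  }, numeric(1))
}

#' Lay out umbrella windows uniformly along the curve
#'
#' Window references alpha_i = (i - 1)/(n_windows - 1) cover [0, 1]
#' uniformly (30 windows give the spacing 1/29). Each window stores its
#' anchor point Z(alpha_i), frozen unit tangent e_i, coordinate-space
#' spring constant K, and the curve length L; the curve-parameter spring
#' constant is kappa = K * L^2.
#'
#' @param curve a reparametrized `"path_curve"`.
#' @param n_windows number of windows (>= 2); default 30.
#' @param K spring constant in coordinate units (kcal/mol/Å^2);
#'   default 0.08.
#' @return a tibble of class `"umbrella_windows"` with columns `window`,
#'   `alpha`, `K`, `kappa`, and list-columns `anchor`, `tangent`; the
#'   curve length is kept in attribute `L`.
#' @examples
#' \dontrun{window_layout(curve, n_windows = 30, K = 0.08)}
#' @export
window_layout <- function(curve, n_windows = 30, K = 0.08) {
  if (n_windows < 2) abort("`n_windows` must be at least 2")
  if (K <= 0) abort("`K` must be positive")
  alpha <- (seq_len(n_windows) - 1) / (n_windows - 1)
  anchors <- path_eval(curve, alpha)
  tangents <- tangent(curve, alpha)
  out <- tibble(
    window = seq_len(n_windows),
    alpha = alpha,
    K = K,
    kappa = K * curve$L^2,
    anchor = lapply(seq_len(n_windows), function(i) anchors[i, ]),
    tangent = lapply(seq_len(n_windows), function(i) tangents[i, ])
  )
  structure(out, L = curve$L, class = c("umbrella_windows", class(out)))
}

#' @rdname window_layout
#' @param windows an `"umbrella_windows"` table.
#' @param i window index.
#' @return `window_at()` returns one window as a plain list with fields
#'   `window`, `alpha`, `anchor`, `tangent`, `K`, `kappa`, `L`.
#' @export
window_at <- function(windows, i) {
  stopifnot(i >= 1, i <= nrow(windows))
  list(window = windows$window[i], alpha = windows$alpha[i],
       anchor = windows$anchor[[i]], tangent = windows$tangent[[i]],
       K = windows$K[i], kappa = windows$kappa[i], L = attr(windows, "L"))
}

as_window <- function(w) {
  if (is_tibble(w)) {
    if (nrow(w) != 1L) abort("expected a single umbrella window")
    return(window_at(w, 1L))
  }
  w
}

# Signed displacement of x from the window anchor along the frozen tangent.
tangent_displacement <- function(w, x) {
  x <- as_coords(x)
  if (length(x) != length(w$anchor)) abort("conformation dimension does not match the window")
  sum((x - w$anchor) * w$tangent)
}

#' Tangent-only umbrella potential
#'
#' Under the local linear approximation the curve near a window anchor is
#' replaced by its tangent line, and the umbrella bias becomes a harmonic
#' potential in the signed tangent displacement d = (x - Z_i) . e_i:
#' U = (K/2) d^2, equivalently (kappa/2)(alpha_lin - alpha_i)^2 with
#' kappa = K L^2 and alpha_lin = alpha_i + d/L. Displacements orthogonal
#' to the tangent contribute exactly zero: only motion along the pathway
#' is restrained.
#'
#' @param w an umbrella window ([window_at()] or one-row window table).
#' @param x a conformation (D-vector).
#' @return energy in kcal/mol (or the K units supplied).
#' @export
umbrella_energy <- function(w, x) {
  w <- as_window(w)
  d <- tangent_displacement(w, x)
  0.5 * w$K * d^2
}

#' Forces from the tangent-only umbrella potential
#'
#' F = -K d e_i, the exact negative gradient of [umbrella_energy()]; the
#' force always points along (plus or minus) the window tangent.
#'
#' @inheritParams umbrella_energy
#' @return numeric D-vector of forces (kcal/mol/Å).
#' @export
umbrella_forces <- function(w, x) {
  w <- as_window(w)
  d <- tangent_displacement(w, x)
  -w$K * d * w$tangent
}

#' Linearized window projection alpha_lin = alpha_i + d/L
#'
#' The curve coordinate a sample in window `w` reports under the same
#' local linearization that generates the umbrella force; this is the
#' quantity WHAM unbiases.
#'
#' @inheritParams umbrella_energy
#' @export
window_alpha <- function(w, x) {
  w <- as_window(w)
  w$alpha + tangent_displacement(w, x) / w$L
}

#' Rigid-body (center and orientation) restraint
#'
#' The tangent umbrella potential is a function of raw Cartesian
#' coordinates and is not invariant under rigid-body motion of the whole
#' molecule; these harmonic restraints remove the six rigid-body degrees
#' of freedom. The center term restrains the unweighted centroid to the
#' reference centroid; the orientation term restrains the rotation angle
#' theta (degrees) of the optimal Kabsch superposition of x onto the
#' reference, extracted from the rotation-matrix trace:
#' cos(theta) = (tr(R) - 1)/2.
#'
#' @param reference reference conformation (3N-vector).
#' @param k_center spring constant on the centroid (kcal/mol/Å^2).
#' @param k_orient spring constant on the orientation angle
#'   (kcal/mol/degree^2).
#' @return an object of class `"rigid_body_restraint"`.
#' @export
rigid_body_restraint <- function(reference, k_center = 1000, k_orient = 200) {
  if (k_center <= 0 || k_orient <= 0) abort("spring constants must be positive")
  structure(list(reference = as_coords(reference), k_center = k_center,
                 k_orient = k_orient),
            class = "rigid_body_restraint")
}

orientation_angle <- function(x, reference) {
  mm <- coord_matrix(x)
  rm_ <- coord_matrix(reference)
  r <- kabsch_rotation(sweep(mm, 2L, colMeans(mm)), sweep(rm_, 2L, colMeans(rm_)))
  cs <- (sum(diag(r)) - 1) / 2
  acos(min(1, max(-1, cs))) * 180 / pi
}

#' Rigid-body restraint energy and gradient
#'
#' energy = (k_center/2) |c(x) - c(ref)|^2 + (k_orient/2) theta(x, ref)^2
#' with c the unweighted centroid and theta the superposition rotation
#' angle in degrees. The centroid gradient is analytic; the orientation
#' gradient is evaluated by central finite differences on theta^2 (the
#' angle enters through the SVD of the 3x3 covariance, for which no
#' closed-form coordinate gradient is exposed here).
#'
#' @param r a [rigid_body_restraint()].
#' @param x conformation (3N-vector).
#' @param gradient if `TRUE`, also return the D-vector gradient.
#' @param h finite-difference step (Å) for the orientation term.
#' @return list with `energy` (kcal/mol), `center_energy`,
#'   `orient_energy`, `angle` (degrees) and, if requested, `gradient`.
#' @export
rigid_body_energy <- function(r, x, gradient = FALSE, h = 1e-5) {
  x <- as_coords(x)
  check_same_dim(x, r$reference)
  xm <- coord_matrix(x)
  rm_ <- coord_matrix(r$reference)
  n <- nrow(xm)
  dc <- colMeans(xm) - colMeans(rm_)
  e_c <- 0.5 * r$k_center * sum(dc^2)
  th <- orientation_angle(x, r$reference)
  e_o <- 0.5 * r$k_orient * th^2
  out <- list(energy = e_c + e_o, center_energy = e_c, orient_energy = e_o,
              angle = th)
  if (gradient) {
    g_c <- rep(dc / n * r$k_center, times = n)  # d/dx of centroid term
    g_o <- numeric(length(x))
    for (j in seq_along(x)) {
      xp <- x; xp[j] <- xp[j] + h
      xmn <- x; xmn[j] <- xmn[j] - h
      g_o[j] <- 0.5 * r$k_orient *
        (orientation_angle(xp, r$reference)^2 -
           orientation_angle(xmn, r$reference)^2) / (2 * h)
    }
    out$gradient <- g_c + g_o
  }
  out
}
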