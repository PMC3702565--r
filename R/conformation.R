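#' Conformations and ensembles
#'
#' A conformation is a D-dimensional coordinate vector. In protein-facing
#' workflows D = 3N: the x, y, z coordinates of N Cα atoms, in Ångström,
#' stored atom-major (x1, y1, z1, x2, ...). Toy systems use small arbitrary
#' D. An ensemble is an ordered set of frames with a common dimension,
#' stored as a frames-by-D numeric matrix.
#'
#' @param coords numeric vector of length D (finite values).
#' @param labels optional integer residue numbers (1-based), length D/3.
#' @return `conformation()` returns a numeric vector of class
#'   `"conformation"` with attributes `n_atoms` (when D is a multiple of 3)
#'   and `labels`.
#' @examples
#' x <- conformation(rnorm(12))
#' n_atoms(x)
#' @export
conformation <- function(coords, labels = NULL) {
  coords <- as.numeric(coords)
  if (length(coords) == 0L || !all(is.finite(coords))) {
    abort("conformation coordinates must be a non-empty finite numeric vector")
  }
  n <- if (length(coords) %% 3L == 0L) length(coords) %/% 3L else NA_integer_
  if (!is.null(labels)) {
    if (is.na(n) || length(labels) != n) {
      abort("`labels` must have one entry per atom (D/3 entries)")
    }
    labels <- as.integer(labels)
  }
  structure(coords, class = "conformation", n_atoms = n, labels = labels)
}

#' @rdname conformation
#' @param x object to query.
#' @export
n_atoms <- function(x) {
  n <- attr(x, "n_atoms")
  if (!is.null(n) && !is.na(n)) return(n)
  d <- if (is.matrix(x)) ncol(x) else length(x)
  if (d %% 3L == 0L) d %/% 3L else NA_integer_
}

# Strip class/attrs down to a plain numeric vector.
as_coords <- function(x) {
  if (is.matrix(x)) return(as.numeric(t(x)))
  as.numeric(x)
}

# D-vector -> N x 3 matrix (protein-facing ops only).
coord_matrix <- function(x) {
  x <- as_coords(x)
  if (length(x) %% 3L != 0L) {
    abort("coordinate vector length must be a multiple of 3")
  }
  matrix(x, ncol = 3L, byrow = TRUE)
}

#' Construct an ensemble of frames
#'
#' @param frames a frames-by-D numeric matrix, a list of equal-length
#'   coordinate vectors, or a single conformation.
#' @param dt optional frame time spacing (ps).
#' @param labels optional residue numbers shared by all frames.
#' @return an object of class `"ensemble"`: a frames-by-D matrix with
#'   attributes `dt` and `labels`.
#' @examples
#' ens <- ensemble(matrix(rnorm(30), nrow = 5), dt = 10)
#' n_frames(ens)
#' @export
ensemble <- function(frames, dt = NULL, labels = NULL) {
  if (is.list(frames)) {
    d <- unique(lengths(frames))
    if (length(d) != 1L) abort("all frames must have the same dimension")
    frames <- do.call(rbind, lapply(frames, as_coords))
  } else if (!is.matrix(frames)) {
    frames <- matrix(as_coords(frames), nrow = 1L)
  }
  storage.mode(frames) <- "double"
  if (nrow(frames) < 1L) abort("an ensemble needs at least one frame")
  if (!all(is.finite(frames))) abort("ensemble coordinates must be finite")
  structure(frames, class = "ensemble", dt = dt, labels = labels)
}

#' @rdname ensemble
#' @param x an ensemble.
#' @export
n_frames <- function(x) nrow(x)

# Frame i as a plain numeric vector.
frame_at <- function(ens, i) as.numeric(unclass(ens)[i, ])

frame_matrix <- function(ens) {
  m <- unclass(ens)
  attributes(m) <- list(dim = dim(m))
  m
}

#' @export
print.ensemble <- function(x, ...) {
  d <- ncol(x)
  n <- n_atoms(x)
  cat(sprintf(
    "<ensemble> %d frame(s), D = %d%s%s\n", nrow(x), d,
    if (!is.na(n)) sprintf(" (N = %d atoms)", n) else "",
    if (!is.null(attr(x, "dt"))) sprintf(", dt = %g ps", attr(x, "dt")) else ""
  ))
  invisible(x)
}

#' @export
print.conformation <- function(x, ...) {
  n <- attr(x, "n_atoms")
  cat(sprintf("<conformation> D = %d%s\n", length(x),
              if (!is.null(n) && !is.na(n)) sprintf(" (N = %d atoms)", n) else ""))
  invisible(x)
}

#' @method as_tibble ensemble
#' @export
as_tibble.ensemble <- function(x, ...) {
  dt <- attr(x, "dt")
  tibble(
    frame = seq_len(nrow(x)),
    time = if (is.null(dt)) NA_real_ else (seq_len(nrow(x)) - 1) * dt,
    coords = lapply(seq_len(nrow(x)), function(i) frame_at(x, i))
  )
}

check_same_dim <- function(a, b, what = "conformations") {
  if (length(as_coords(a)) != length(as_coords(b))) {
    abort(sprintf("%s have mismatched dimensions (%d vs %d)", what,
                  length(as_coords(a)), length(as_coords(b))))
  }
  invisible(TRUE)
}
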