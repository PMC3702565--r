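#' Root-mean-square deviation between two conformations
#'
#' Computed directly on the coordinates as supplied: no superposition is
#' performed. Compose with [kabsch_align()] to obtain the aligned RMSD.
#'
#' @param a,b conformations (numeric D-vectors, D = 3N) with equal N.
#' @return non-negative RMSD in the coordinate units (Å).
#' @examples
#' a <- rnorm(30); rmsd(a, a)
#' @export
rmsd <- function(a, b) {
  check_same_dim(a, b)
  d <- as_coords(a) - as_coords(b)
  if (length(d) %% 3L != 0L) {
    abort("rmsd expects 3N coordinate vectors")
  }
  sqrt(sum(d^2) / (length(d) / 3L))
}

# Optimal proper rotation (Kabsch, SVD form) taking centered mobile onto
# centered reference. Reflections are excluded by flipping the sign of the
# singular vector with the smallest singular value when det < 0, so the
# result is always a rotation even for planar/degenerate point sets.
kabsch_rotation <- function(mob_c, ref_c) {
  h <- crossprod(mob_c, ref_c)       # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  corr <- diag(c(1, 1, d))
  s$v %*% corr %*% t(s$u)            # rotation: x_aligned = x %*% t(R)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference`, with all atoms weighted equally (the Cα-only
#' representation used throughout the package).
#'
#' @param mobile,reference conformations (3N-vectors) with equal N >= 3.
#' @return a list with components `aligned` (the transformed mobile
#'   conformation, same attributes as `mobile`), `rmsd` (the minimized
#'   value, Å), `rotation` (3x3 proper rotation matrix) and `translation`.
#' @examples
#' ref <- rnorm(12)
#' fit <- kabsch_align(ref, ref)
#' fit$rmsd
#' @export
kabsch_align <- function(mobile, reference) {
  check_same_dim(mobile, reference)
  mm <- coord_matrix(mobile)
  rm_ <- coord_matrix(reference)
  n <- nrow(mm)
  if (n < 3L) abort("superposition needs at least 3 atoms")
  cm <- colMeans(mm)
  cr <- colMeans(rm_)
  mob_c <- sweep(mm, 2L, cm)
  ref_c <- sweep(rm_, 2L, cr)
  if (sum(ref_c^2) < 1e-24) abort("reference conformation is degenerate (zero extent)")
  r <- kabsch_rotation(mob_c, ref_c)
  aligned_m <- mob_c %*% t(r)
  aligned_m <- sweep(aligned_m, 2L, cr, `+`)
  val <- sqrt(sum((aligned_m - rm_)^2) / n)
  aligned <- as.numeric(t(aligned_m))
  attributes(aligned) <- attributes(as_coords(mobile))
  if (inherits(mobile, "conformation")) {
    aligned <- conformation(aligned, labels = attr(mobile, "labels"))
  }
  list(aligned = aligned, rmsd = val, rotation = r,
       translation = cr - as.numeric(cm %*% t(r)))
}

# Align every frame of an ensemble to a reference; returns a plain matrix.
align_frames <- function(frames, reference) {
  out <- frames
  for (i in seq_len(nrow(frames))) {
    out[i, ] <- kabsch_align(frames[i, ], reference)$aligned
  }
  out
}

#' Mean conformation of the trailing part of an ensemble
#'
#' Each frame in the trailing `last_fraction` of the ensemble is
#' superposed onto `reference` with [kabsch_align()], and the aligned
#' coordinates are averaged component-wise. This is the standard way of
#' summarizing the late, equilibrated stage of a trajectory (e.g. the last
#' 40 ns of a 100 ns run corresponds to `last_fraction = 0.4`).
#'
#' @param ens an [ensemble()].
#' @param reference conformation to superpose onto.
#' @param last_fraction fraction of trailing frames to keep, in (0, 1].
#' @return the mean conformation (numeric 3N-vector).
#' @export
mean_conformation <- function(ens, reference, last_fraction = 1) {
  if (!is.matrix(ens)) ens <- ensemble(ens)
  if (last_fraction <= 0 || last_fraction > 1) {
    abort("`last_fraction` must be in (0, 1]")
  }
  n <- nrow(ens)
  keep <- max(1L, ceiling(last_fraction * n))
  idx <- seq.int(n - keep + 1L, n)
  if (length(idx) == 0L) abort("empty frame selection")
  m <- frame_matrix(ens)[idx, , drop = FALSE]
  colMeans(align_frames(m, reference))
}
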