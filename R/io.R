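# File formats. Every writer emits a header line
#   # pathfe <version> | <kind> | config=<hash> | seed=<seed>
# so artifacts record the tool version, a hash of the generating
# configuration, and the seeds involved (the reproducibility contract).
# Units: alpha dimensionless in [0, 1]; arc length and coordinates in Å;
# energies kcal/mol in protein-facing paths and kT units in toy paths.

file_header <- function(kind, config = list(), seed = NA) {
  sprintf("# pathfe %s | %s | config=%s | seed=%s",
          as.character(packageVersion("pathfe")), kind,
          hash(config), paste(seed, collapse = ","))
}

skip_comments <- function(lines) lines[!grepl("^\\s*(#|$)", lines)]

fmt <- function(x) sprintf("%.17g", x)

num_or_na <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out
}

#' Read Cα coordinates from a (multi-model) PDB file
#'
#' Extracts the atoms named "CA" from every MODEL of a PDB file (via the
#' bio3d reader) and returns them as an ensemble of 3N-vectors with
#' 1-based residue-number labels.
#'
#' @param path PDB file path.
#' @return an [ensemble()] with residue `labels`.
#' @export
read_pdb_ca <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB files requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  if (length(sel$atom) == 0L) abort(sprintf("no CA atoms in '%s'", path))
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  labels <- as.integer(pdb$atom$resno[sel$atom])
  ensemble(unclass(xyz), labels = labels)
}

#' Write an ensemble as a Cα-only multi-model PDB file
#'
#' @param ens an [ensemble()] (or single conformation) with D = 3N;
#'   residue labels are taken from the ensemble or `labels`.
#' @param path output file.
#' @param labels residue numbers (default: ensemble labels, else 1..N).
#' @param seed seed recorded in the REMARK header.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(ens, path, labels = NULL, seed = NA) {
  if (!is.matrix(ens)) ens <- ensemble(ens)
  m <- frame_matrix(ens)
  n <- ncol(m) %/% 3L
  if (ncol(m) %% 3L != 0L) abort("PDB output needs 3N coordinate vectors")
  if (is.null(labels)) labels <- attr(ens, "labels")
  if (is.null(labels)) labels <- seq_len(n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   1 %s", file_header("ca-trajectory", list(n = n), seed)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(sprintf("MODEL %8d", i), con)
    fm <- matrix(m[i, ], ncol = 3L, byrow = TRUE)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), labels, fm[, 1], fm[, 2], fm[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Plain-text trajectory files
#'
#' One frame per block: N lines of whitespace-separated coordinates
#' (3 per line for 3N systems, one D-vector line otherwise), blank line
#' between frames, `#` header lines carrying D, the atom count, dt and
#' the reproducibility header.
#'
#' @param ens an [ensemble()].
#' @param path file path.
#' @param seed seed recorded in the header.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns an [ensemble()].
#' @export
write_trajectory <- function(ens, path, seed = NA) {
  if (!is.matrix(ens)) ens <- ensemble(ens)
  m <- frame_matrix(ens)
  d <- ncol(m)
  per_line <- if (d %% 3L == 0L) 3L else d
  dt <- attr(ens, "dt")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header("trajectory", list(d = d), seed), con)
  writeLines(sprintf("# D %d per_line %d dt %s", d, per_line,
                     if (is.null(dt)) "NA" else fmt(dt)), con)
  for (i in seq_len(nrow(m))) {
    rows <- matrix(m[i, ], ncol = per_line, byrow = TRUE)
    writeLines(apply(rows, 1L, function(r) paste(fmt(r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# D ", lines, value = TRUE)
  if (length(hdr) != 1L) abort(sprintf("'%s': missing trajectory dimension header", path))
  tok <- strsplit(trimws(sub("^#", "", hdr)), "\\s+")[[1]]
  d <- as.integer(tok[2])
  dt <- suppressWarnings(as.numeric(tok[6]))
  body <- lines[!grepl("^\\s*#", lines)]
  frames <- list()
  buf <- numeric(0)
  flush_frame <- function() {
    if (length(buf) == 0L) return()
    if (length(buf) != d) {
      abort(sprintf("'%s': frame %d has %d values, expected %d", path,
                    length(frames) + 1L, length(buf), d))
    }
    frames[[length(frames) + 1L]] <<- buf
    buf <<- numeric(0)
  }
  for (ln in body) {
    if (grepl("^\\s*$", ln)) flush_frame()
    else buf <- c(buf, as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
  }
  flush_frame()
  if (length(frames) == 0L) abort(sprintf("'%s': no frames", path))
  ensemble(frames, dt = if (is.finite(dt)) dt else NULL)
}

#' Path-curve files
#'
#' Self-describing text format storing the dimension, basis size, total
#' length, parametrization flag, basis coefficients and the arc-length
#' table; the round trip is lossless to full double precision.
#'
#' @param curve a `"path_curve"`.
#' @param path file path.
#' @param seed seed recorded in the header.
#' @return `write_path_curve()` returns `path` invisibly;
#'   `read_path_curve()` returns the curve.
#' @export
write_path_curve <- function(curve, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header("path-curve", list(d = curve$dim, P = curve$P), seed), con)
  writeLines(sprintf("D %d", curve$dim), con)
  writeLines(sprintf("P %d", curve$P), con)
  writeLines(sprintf("L %s", fmt(curve$L)), con)
  writeLines(sprintf("uniform %d", as.integer(isTRUE(curve$uniform))), con)
  writeLines(sprintf("objective %s", fmt(curve$objective)), con)
  writeLines(sprintf("coeffs %d", nrow(curve$coeffs)), con)
  writeLines(apply(curve$coeffs, 1L, function(r) paste(fmt(r), collapse = " ")), con)
  writeLines(sprintf("arc %d", length(curve$arc$t)), con)
  writeLines(paste(fmt(curve$arc$t), fmt(curve$arc$s)), con)
  invisible(path)
}

#' @rdname write_path_curve
#' @export
read_path_curve <- function(path) {
  lines <- skip_comments(readLines(path))
  kv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    if (is.na(ln)) abort(sprintf("'%s': missing '%s' record", path, key))
    strsplit(trimws(ln), "\\s+")[[1]][-1]
  }
  d <- as.integer(kv("D")); p <- as.integer(kv("P"))
  n_cf <- as.integer(kv("coeffs"))
  i_cf <- grep("^coeffs ", lines)[1]
  coeffs <- do.call(rbind, lapply(lines[(i_cf + 1L):(i_cf + n_cf)], function(ln) {
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  }))
  if (ncol(coeffs) != d) abort(sprintf("'%s': coefficient rows have wrong width", path))
  n_arc <- as.integer(kv("arc"))
  i_arc <- grep("^arc ", lines)[1]
  arc_rows <- do.call(rbind, lapply(lines[(i_arc + 1L):(i_arc + n_arc)], function(ln) {
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  }))
  cv <- structure(
    list(dim = d, P = p, coeffs = coeffs, t_nodes = NULL,
         objective = num_or_na(kv("objective")), iterations = NA_integer_,
         converged = NA, uniform = as.integer(kv("uniform")) == 1L,
         arc = list(t = arc_rows[, 1], s = arc_rows[, 2]),
         L = as.numeric(kv("L"))),
    class = "path_curve"
  )
  cv
}

#' Umbrella-window files
#'
#' Per-window records (index, alpha, K, kappa) followed by the anchor and
#' tangent vectors; round-trip lossless, suitable for export to external
#' restraint engines.
#'
#' @param windows an `"umbrella_windows"` table from [window_layout()].
#' @param path file path.
#' @param seed seed recorded in the header.
#' @export
write_windows <- function(windows, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header("umbrella-windows",
                         list(n = nrow(windows), K = windows$K[1]), seed), con)
  writeLines(sprintf("L %s", fmt(attr(windows, "L"))), con)
  writeLines(sprintf("n_windows %d", nrow(windows)), con)
  for (i in seq_len(nrow(windows))) {
    w <- window_at(windows, i)
    writeLines(sprintf("window %d %s %s %s", w$window, fmt(w$alpha),
                       fmt(w$K), fmt(w$kappa)), con)
    writeLines(paste("anchor", paste(fmt(w$anchor), collapse = " ")), con)
    writeLines(paste("tangent", paste(fmt(w$tangent), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  lines <- skip_comments(readLines(path))
  l_val <- as.numeric(strsplit(grep("^L ", lines, value = TRUE)[1], "\\s+")[[1]][2])
  wi <- grep("^window ", lines)
  rows <- lapply(wi, function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    anchor <- as.numeric(strsplit(trimws(lines[i + 1L]), "\\s+")[[1]][-1])
    tang <- as.numeric(strsplit(trimws(lines[i + 2L]), "\\s+")[[1]][-1])
    tibble(window = as.integer(tok[2]), alpha = as.numeric(tok[3]),
           K = as.numeric(tok[4]), kappa = as.numeric(tok[5]),
           anchor = list(anchor), tangent = list(tang))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, L = l_val, class = c("umbrella_windows", class(out)))
}

#' Sample and profile tables
#'
#' Columnar text formats: samples as (window, cycle, alpha) rows plus
#' per-window metadata lines; profiles as (alpha, free_energy,
#' std_error) rows.
#'
#' @param all_samples window-samples tibble (see [window_samples()]).
#' @param path file path.
#' @param seed seed recorded in the header.
#' @export
write_samples <- function(all_samples, path, seed = NA) {
  ws <- as_window_samples(all_samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header("window-samples", list(n = nrow(ws)), seed), con)
  for (i in seq_len(nrow(ws))) {
    writeLines(sprintf("meta %d %s %s %s", ws$window[i], fmt(ws$alpha_ref[i]),
                       fmt(ws$kappa[i]), fmt(ws$cut[i])), con)
  }
  writeLines("window step alpha", con)
  for (i in seq_len(nrow(ws))) {
    s <- ws$samples[[i]]
    writeLines(sprintf("%d %d %s", ws$window[i], seq_along(s), fmt(s)), con)
  }
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  lines <- skip_comments(readLines(path))
  meta_ln <- grep("^meta ", lines, value = TRUE)
  meta <- do.call(rbind, lapply(meta_ln, function(ln) {
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][-1])
  }))
  body <- lines[!grepl("^(meta |window step alpha)", lines)]
  tok <- strsplit(trimws(body), "\\s+")
  win <- vapply(tok, function(t) as.integer(t[1]), integer(1))
  alpha <- vapply(tok, function(t) as.numeric(t[3]), numeric(1))
  dplyr::bind_rows(lapply(seq_len(nrow(meta)), function(i) {
    w <- as.integer(meta[i, 1])
    window_samples(w, meta[i, 2], meta[i, 3], alpha[win == w],
                   cut = meta[i, 4])
  }))
}

#' @rdname write_samples
#' @param profile a `"fep"` profile.
#' @export
write_profile <- function(profile, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header("free-energy-profile",
                         list(n = nrow(profile), kT = attr(profile, "kT")),
                         seed), con)
  writeLines(sprintf("# kT %s", fmt(attr(profile, "kT"))), con)
  writeLines("alpha free_energy std_error", con)
  writeLines(sprintf("%s %s %s", fmt(profile$alpha), fmt(profile$free_energy),
                     fmt(profile$std_error)), con)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  kt_ln <- grep("^# kT ", lines, value = TRUE)
  kT <- if (length(kt_ln)) as.numeric(strsplit(kt_ln[1], "\\s+")[[1]][3]) else 1
  body <- skip_comments(lines)
  body <- body[!grepl("^alpha ", body)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  out <- tibble(alpha = m[, 1], free_energy = m[, 2], std_error = m[, 3])
  structure(out, kT = kT, iterations = NA_integer_, converged = NA,
            f_windows = numeric(0), n_samples = NA_integer_,
            class = c("fep", class(out)))
}
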