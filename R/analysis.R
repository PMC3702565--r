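#' Projection time series of a trajectory onto the pathway
#'
#' Each frame is rigid-body aligned to the reference (when supplied) and
#' mapped to its curve parameter by the nearest-point projection
#' [project()]; the resulting alpha(t) series is how spontaneous
#' transitions between the two endpoint states are visualized.
#'
#' @param ens an [ensemble()].
#' @param curve a reparametrized `"path_curve"`.
#' @param reference conformation for alignment, or `NULL` to project
#'   frames as-is.
#' @return tibble with columns `frame`, `time` (NA when the ensemble has
#'   no `dt`), `alpha`.
#' @export
projection_timeseries <- function(ens, curve, reference = NULL) {
  if (!is.matrix(ens)) ens <- ensemble(ens)
  m <- frame_matrix(ens)
  if (ncol(m) != curve$dim) abort("frame dimension does not match the curve")
  if (!is.null(reference)) m <- align_frames(m, reference)
  dt <- attr(ens, "dt")
  tibble(
    frame = seq_len(nrow(m)),
    time = if (is.null(dt)) NA_real_ else (seq_len(nrow(m)) - 1) * dt,
    alpha = project(curve, m)
  )
}

#' Domain definitions
#'
#' A named set of 1-based residue ranges. `adk_domains()` returns the
#' classic three-domain decomposition of adenylate kinase: LID (residues
#' 122-159), AMPbd (30-59) and CORE (1-29, 60-121, 160-214).
#'
#' @param ... named integer vectors of residue numbers, e.g.
#'   `LID = 122:159`.
#' @return a named list of class `"domain_definition"`.
#' @export
domain_definition <- function(...) {
  doms <- list(...)
  if (length(doms) == 0L || is.null(names(doms)) || any(names(doms) == "")) {
    abort("domains must be named residue-number vectors")
  }
  doms <- lapply(doms, function(d) sort(unique(as.integer(d))))
  if (any(lengths(doms) == 0L)) abort("domains must be non-empty")
  structure(doms, class = "domain_definition")
}

#' @rdname domain_definition
#' @export
adk_domains <- function() {
  domain_definition(
    LID = 122:159,
    AMPbd = 30:59,
    CORE = c(1:29, 60:121, 160:214)
  )
}

#' Distances between domain centers along a trajectory
#'
#' The center of each domain is the unweighted mean position of its Cα
#' atoms; the per-frame distances between centers (LID-CORE and
#' AMPbd-CORE by default) provide a reduced two-coordinate picture of
#' open/closed conformational transitions.
#'
#' @param ens an [ensemble()] whose frames carry residue `labels` (or
#'   pass `labels`).
#' @param domains a [domain_definition()].
#' @param pairs list of length-2 character vectors naming the domain
#'   pairs; default: every pair involving the last domain (the CORE
#'   convention) or all pairs when only two domains exist.
#' @param labels residue numbers overriding the ensemble attribute.
#' @return tibble with columns `frame`, `time`, `pair`, `distance` (Å).
#' @export
domain_distances <- function(ens, domains = adk_domains(), pairs = NULL,
                             labels = NULL) {
  if (!is.matrix(ens)) ens <- ensemble(ens)
  if (is.null(labels)) labels <- attr(ens, "labels")
  if (is.null(labels)) abort("residue labels are required (ensemble `labels`)")
  labels <- as.integer(labels)
  m <- frame_matrix(ens)
  if (ncol(m) != 3L * length(labels)) {
    abort("labels length does not match the number of atoms")
  }
  idx <- lapply(names(domains), function(nm) {
    hit <- which(labels %in% domains[[nm]])
    if (length(hit) == 0L) {
      abort(sprintf("domain '%s' resolves no residues", nm))
    }
    hit
  })
  names(idx) <- names(domains)
  if (is.null(pairs)) {
    nms <- names(domains)
    anchor <- nms[length(nms)]
    others <- setdiff(nms, anchor)
    pairs <- lapply(others, function(o) c(o, anchor))
  }
  dt <- attr(ens, "dt")
  out <- lapply(pairs, function(pr) {
    if (!all(pr %in% names(idx))) {
      abort(sprintf("unknown domain in pair %s-%s", pr[1], pr[2]))
    }
    d <- vapply(seq_len(nrow(m)), function(i) {
      fm <- matrix(m[i, ], ncol = 3L, byrow = TRUE)
      c1 <- colMeans(fm[idx[[pr[1]]], , drop = FALSE])
      c2 <- colMeans(fm[idx[[pr[2]]], , drop = FALSE])
      sqrt(sum((c1 - c2)^2))
    }, numeric(1))
    tibble(
      frame = seq_len(nrow(m)),
      time = if (is.null(dt)) NA_real_ else (seq_len(nrow(m)) - 1) * dt,
      pair = paste(pr, collapse = "-"),
      distance = d
    )
  })
  dplyr::bind_rows(out)
}

#' RMSD table of ensemble means against reference structures
#'
#' For each ensemble, the mean conformation over its trailing
#' `last_fraction` of frames ([mean_conformation()]) is superposed onto
#' each reference and the aligned RMSD reported — the standard summary
#' comparing the late stage of several trajectories against endpoint
#' crystal structures.
#'
#' @param ensembles named list of [ensemble()]s.
#' @param references named list of reference conformations.
#' @param last_fraction trailing fraction averaged (e.g. 0.4 for the last
#'   40 ns of a 100 ns run).
#' @return tibble with columns `ensemble`, `reference`, `rmsd` (Å);
#'   `tidyr::pivot_wider()` reshapes it references-by-ensembles.
#' @export
rmsd_table <- function(ensembles, references, last_fraction = 0.4) {
  if (is.null(names(ensembles)) || is.null(names(references))) {
    abort("`ensembles` and `references` must be named")
  }
  align_ref <- references[[1]]
  rows <- list()
  for (en in names(ensembles)) {
    mc <- mean_conformation(ensembles[[en]], align_ref, last_fraction)
    for (rn in names(references)) {
      rows[[length(rows) + 1L]] <- tibble(
        ensemble = en, reference = rn,
        rmsd = kabsch_align(mc, references[[rn]])$rmsd
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Salt-bridge assignment criterion
#'
#' A salt bridge is assigned only when a directional hydrogen bond links
#' the two side chains: a donor nitrogen (Lys NZ; Arg NE/NH1/NH2) within
#' `distance_cutoff` of an acceptor oxygen (Asp OD1/OD2; Glu OE1/OE2),
#' with a donor-H...acceptor angle of at least `angle_cutoff`. When the
#' frames carry no hydrogens the detector falls back to the heavy-atom
#' distance plus an antecedent-carbon geometry proxy, and flags it.
#'
#' @param distance_cutoff donor-acceptor heavy-atom cutoff (Å).
#' @param angle_cutoff donor-H...acceptor angle cutoff (degrees).
#' @return a list of class `"salt_bridge_criterion"`.
#' @export
salt_bridge_criterion <- function(distance_cutoff = 3.5, angle_cutoff = 130) {
  if (distance_cutoff <= 0 || angle_cutoff <= 0) {
    abort("cutoffs must be positive")
  }
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff,
                 donors = list(LYS = "NZ", ARG = c("NE", "NH1", "NH2")),
                 acceptors = list(ASP = c("OD1", "OD2"),
                                  GLU = c("OE1", "OE2"))),
            class = "salt_bridge_criterion")
}

vec_angle_deg <- function(v1, v2) {
  cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(1, max(-1, cs))) * 180 / pi
}

#' Detect side-chain salt bridges in full-atom frames
#'
#' @param frames a data frame (single frame) or list of data frames, each
#'   with columns `resno` (residue number), `resname` (3-letter residue
#'   name), `atom` (atom name), `x`, `y`, `z` (Å).
#' @param criterion a [salt_bridge_criterion()].
#' @return a list with `contacts` (tibble: frame, donor_resno,
#'   donor_resname, acceptor_resno, acceptor_resname, distance, angle,
#'   proxy) and `occupancy` (tibble: pair, occupancy — fraction of frames
#'   in which the pair is bridged).
#' @export
detect_salt_bridges <- function(frames, criterion = salt_bridge_criterion()) {
  if (is.data.frame(frames)) frames <- list(frames)
  need <- c("resno", "resname", "atom", "x", "y", "z")
  contacts <- list()
  for (fi in seq_along(frames)) {
    fr <- as.data.frame(frames[[fi]])
    if (!all(need %in% names(fr))) {
      abort(sprintf("frame %d lacks columns: %s", fi,
                    paste(setdiff(need, names(fr)), collapse = ", ")))
    }
    fr$resname <- toupper(fr$resname)
    fr$atom <- toupper(fr$atom)
    has_h <- any(grepl("^H", fr$atom))
    don <- fr[mapply(function(rn, an) {
      rn %in% names(criterion$donors) && an %in% criterion$donors[[rn]]
    }, fr$resname, fr$atom), , drop = FALSE]
    acc <- fr[mapply(function(rn, an) {
      rn %in% names(criterion$acceptors) && an %in% criterion$acceptors[[rn]]
    }, fr$resname, fr$atom), , drop = FALSE]
    if (nrow(don) == 0L || nrow(acc) == 0L) next
    for (di in seq_len(nrow(don))) {
      dpos <- as.numeric(don[di, c("x", "y", "z")])
      dres <- don$resno[di]
      # protons (or antecedent carbon for the proxy) bonded to this donor
      same_res <- fr[fr$resno == dres, , drop = FALSE]
      datoms <- same_res[, c("x", "y", "z")]
      dd <- sqrt(rowSums(sweep(as.matrix(datoms), 2L, dpos)^2))
      hyd <- same_res[grepl("^H", same_res$atom) & dd < 1.25 & dd > 1e-6, ,
                      drop = FALSE]
      ante <- same_res[grepl("^C", same_res$atom) & dd < 1.8 & dd > 1e-6, ,
                       drop = FALSE]
      for (ai in seq_len(nrow(acc))) {
        if (acc$resno[ai] == dres) next
        apos <- as.numeric(acc[ai, c("x", "y", "z")])
        dist <- sqrt(sum((dpos - apos)^2))
        if (dist > criterion$distance_cutoff) next
        ang <- NA_real_
        proxy <- FALSE
        ok <- FALSE
        if (has_h && nrow(hyd) > 0L) {
          # best donor-H...acceptor angle (at the hydrogen)
          angs <- vapply(seq_len(nrow(hyd)), function(hi) {
            hpos <- as.numeric(hyd[hi, c("x", "y", "z")])
            vec_angle_deg(dpos - hpos, apos - hpos)
          }, numeric(1))
          ang <- max(angs)
          ok <- ang >= criterion$angle_cutoff
        } else if (nrow(ante) > 0L) {
          # no hydrogens: antecedent-carbon geometry proxy, angle at N
          cpos <- as.numeric(ante[1L, c("x", "y", "z")])
          ang <- vec_angle_deg(dpos - cpos, apos - dpos)
          proxy <- TRUE
          ok <- ang <= (180 - criterion$angle_cutoff)
        } else {
          proxy <- TRUE
          ok <- TRUE   # distance-only fallback
        }
        if (ok) {
          contacts[[length(contacts) + 1L]] <- tibble(
            frame = fi,
            donor_resno = dres, donor_resname = don$resname[di],
            acceptor_resno = acc$resno[ai],
            acceptor_resname = acc$resname[ai],
            distance = dist, angle = ang, proxy = proxy
          )
        }
      }
    }
  }
  contacts <- if (length(contacts)) dplyr::bind_rows(contacts) else
    tibble(frame = integer(0), donor_resno = integer(0),
           donor_resname = character(0), acceptor_resno = integer(0),
           acceptor_resname = character(0), distance = numeric(0),
           angle = numeric(0), proxy = logical(0))
  # one hit per residue pair per frame for occupancy
  occ <- contacts |>
    dplyr::mutate(pair = paste0(.data$donor_resname, .data$donor_resno, "-",
                                .data$acceptor_resname, .data$acceptor_resno)) |>
    dplyr::distinct(.data$frame, .data$pair) |>
    dplyr::count(.data$pair, name = "n_frames") |>
    dplyr::mutate(occupancy = .data$n_frames / length(frames))
  list(contacts = contacts, occupancy = occ)
}
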