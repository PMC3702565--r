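test_that("projection time series maps on-curve frames to their parameters", {
  cv <- random_test_curve(d = 6, P = 1, seed = 70)
  al <- seq(0, 1, by = 0.1)
  ens <- ensemble(path_eval(cv, al), dt = 2)
  ts <- projection_timeseries(ens, cv)
  expect_equal(ts$alpha, al, tolerance = 1e-6)
  expect_equal(ts$time, (0:10) * 2)
})

test_that("projection after alignment is invariant to rigid-body motion", {
  # a 3N-dimensional curve so frames can be superposed
  set.seed(71)
  coeffs <- rbind(rnorm(12, sd = 2), rnorm(12, sd = 5), rnorm(12))
  cv <- reparametrize(path_curve(coeffs, P = 1))
  al <- seq(0.1, 0.9, by = 0.2)
  frames <- path_eval(cv, al)
  ref <- drop(path_eval(cv, 0))
  th <- 0.7
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  moved <- t(apply(frames, 1, function(f) {
    m <- matrix(f, ncol = 3, byrow = TRUE) %*% t(rz)
    as.numeric(t(sweep(m, 2, c(4, -2, 1), `+`)))
  }))
  t_orig <- projection_timeseries(ensemble(frames), cv, reference = ref)
  t_moved <- projection_timeseries(ensemble(moved), cv, reference = ref)
  expect_lt(max(abs(t_moved$alpha - t_orig$alpha)), 1e-8)
})

test_that("domain distances equal direct per-range computations", {
  # two single-residue domains 7 apart
  coords <- c(0, 0, 0, 7, 0, 0)
  ens <- ensemble(coords, labels = c(1, 2))
  dd <- domain_distances(ens, domain_definition(A = 1, B = 2),
                         pairs = list(c("A", "B")))
  expect_equal(dd$distance, 7)
  # all atoms at the origin
  ens0 <- ensemble(rep(0, 12), labels = 1:4)
  dd0 <- domain_distances(ens0, domain_definition(A = 1:2, B = 3:4),
                          pairs = list(c("A", "B")))
  expect_equal(dd0$distance, 0)
  # random 214-residue conformation with the standard three domains
  set.seed(72)
  x <- rnorm(3 * 214, sd = 10)
  ens214 <- ensemble(x, labels = 1:214)
  dd3 <- domain_distances(ens214)
  expect_setequal(unique(dd3$pair), c("LID-CORE", "AMPbd-CORE"))
  m <- matrix(x, ncol = 3, byrow = TRUE)
  doms <- adk_domains()
  ctr <- function(rr) colMeans(m[rr, , drop = FALSE])
  expect_equal(dd3$distance[dd3$pair == "LID-CORE"],
               sqrt(sum((ctr(doms$LID) - ctr(doms$CORE))^2)))
  expect_equal(dd3$distance[dd3$pair == "AMPbd-CORE"],
               sqrt(sum((ctr(doms$AMPbd) - ctr(doms$CORE))^2)))
  expect_error(domain_distances(ens214, domain_definition(X = 300:310)),
               "resolves no residues")
})

test_that("rmsd_table compares trailing means against each reference", {
  set.seed(73)
  a <- rnorm(3 * 30, sd = 3)
  b <- a + rnorm(90, sd = 2)
  ens_a <- ensemble(matrix(rep(a, 10), nrow = 10, byrow = TRUE))
  tab <- rmsd_table(list(E1 = ens_a), list(A = a, B = b), last_fraction = 0.5)
  expect_equal(tab$rmsd[tab$reference == "A"], 0, tolerance = 1e-10)
  expect_equal(tab$rmsd[tab$reference == "B"], kabsch_align(a, b)$rmsd,
               tolerance = 1e-10)
  # invariance under a rigid transform of the ensemble
  th <- 1.1
  rz <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
               3, 3, byrow = TRUE)
  moved <- t(apply(unclass(ens_a), 1, function(f) {
    as.numeric(t(sweep(matrix(f, ncol = 3, byrow = TRUE) %*% t(rz),
                       2, c(1, 2, 3), `+`)))
  }))
  tab2 <- rmsd_table(list(E1 = ensemble(moved)), list(A = a, B = b),
                     last_fraction = 0.5)
  expect_equal(tab2$rmsd, tab$rmsd, tolerance = 1e-8)
})

test_that("salt bridges require both distance and hydrogen-bond geometry", {
  mk_frame <- function(no_angle = FALSE, far = FALSE) {
    d_no <- if (far) 6 else 2.8
    # LYS donor with NZ at origin, H pointing at the acceptor (or away)
    h <- if (no_angle) c(0, 1, 0) else c(d_no / 2.8, 0, 0)
    data.frame(
      resno = c(1, 1, 1, 2, 2),
      resname = c("LYS", "LYS", "LYS", "ASP", "ASP"),
      atom = c("NZ", "CE", "HZ1", "OD1", "CG"),
      x = c(0, -1.5, h[1], d_no, d_no + 1),
      y = c(0, 0, h[2], 0, 0.5),
      z = c(0, 0, h[3], 0, 0)
    )
  }
  hit <- detect_salt_bridges(mk_frame())
  expect_equal(nrow(hit$contacts), 1)
  expect_equal(hit$contacts$donor_resno, 1)
  expect_false(hit$contacts$proxy)
  expect_equal(hit$occupancy$occupancy, 1)
  # same pair at 6 A: rejected on distance
  expect_equal(nrow(detect_salt_bridges(mk_frame(far = TRUE))$contacts), 0)
  # hydrogen pointing away: rejected on angle
  expect_equal(nrow(detect_salt_bridges(mk_frame(no_angle = TRUE))$contacts), 0)
  # no hydrogens at all: heavy-atom + antecedent-carbon proxy, flagged
  fr <- mk_frame(); fr <- fr[fr$atom != "HZ1", ]
  hit2 <- detect_salt_bridges(fr)
  expect_equal(nrow(hit2$contacts), 1)
  expect_true(hit2$contacts$proxy)
})

test_that("salt-bridge detection matches an exhaustive pair-scan oracle", {
  set.seed(74)
  crit <- salt_bridge_criterion()
  # decoy set: random LYS/ARG/ASP/GLU side-chain tips in a small box
  n_res <- 24
  resnames <- sample(c("LYS", "ARG", "ASP", "GLU"), n_res, replace = TRUE)
  rows <- list()
  for (i in seq_len(n_res)) {
    base <- runif(3, 0, 14)
    if (resnames[i] %in% c("LYS", "ARG")) {
      nm <- if (resnames[i] == "LYS") "NZ" else "NH1"
      hdir <- rnorm(3); hdir <- hdir / sqrt(sum(hdir^2))
      rows[[length(rows) + 1L]] <- data.frame(
        resno = i, resname = resnames[i],
        atom = c(nm, "HZ1"),
        x = c(base[1], base[1] + hdir[1]),
        y = c(base[2], base[2] + hdir[2]),
        z = c(base[3], base[3] + hdir[3]))
    } else {
      nm <- if (resnames[i] == "ASP") "OD1" else "OE1"
      rows[[length(rows) + 1L]] <- data.frame(
        resno = i, resname = resnames[i], atom = nm,
        x = base[1], y = base[2], z = base[3])
    }
  }
  fr <- do.call(rbind, rows)
  got <- detect_salt_bridges(fr, crit)$contacts
  # brute-force oracle over every donor-acceptor combination
  expected <- 0L
  don <- fr[fr$atom %in% c("NZ", "NH1"), ]
  acc <- fr[fr$atom %in% c("OD1", "OE1"), ]
  for (i in seq_len(nrow(don))) for (j in seq_len(nrow(acc))) {
    dpos <- as.numeric(don[i, c("x", "y", "z")])
    apos <- as.numeric(acc[j, c("x", "y", "z")])
    hrow <- fr[fr$resno == don$resno[i] & fr$atom == "HZ1", ]
    hpos <- as.numeric(hrow[1, c("x", "y", "z")])
    dist <- sqrt(sum((dpos - apos)^2))
    v1 <- dpos - hpos; v2 <- apos - hpos
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (dist <= crit$distance_cutoff && ang >= crit$angle_cutoff) {
      expected <- expected + 1L
    }
  }
  expect_equal(nrow(got), expected)
})
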