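#' Bundle one window's biased samples for WHAM
#'
#' @param window window index.
#' @param alpha_ref the window's reference curve parameter alpha_i.
#' @param kappa curve-parameter spring constant (energy units; kappa =
#'   K L^2 when the coordinate-space constant is K).
#' @param samples ordered alpha samples from that window.
#' @param cut equilibration fraction discarded from the start of the
#'   series; the default 0.25 mirrors discarding the first quarter of
#'   each production run.
#' @return one-row tibble with a `samples` list-column; rows from
#'   several windows can be bound with `dplyr::bind_rows()`.
#' @export
window_samples <- function(window, alpha_ref, kappa, samples, cut = 0.25) {
  if (kappa <= 0) abort("`kappa` must be positive")
  if (cut < 0 || cut >= 1) abort("`cut` must be in [0, 1)")
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) abort("samples must be finite")
  tibble(window = as.integer(window), alpha_ref = alpha_ref, kappa = kappa,
         cut = cut, samples = list(samples))
}

# Samples retained after the equilibration cut.
retained_samples <- function(ws_row) {
  s <- ws_row$samples[[1]]
  drop_n <- floor(ws_row$cut * length(s))
  if (drop_n >= length(s)) abort("equilibration cut leaves no samples")
  s[(drop_n + 1L):length(s)]
}

# Canonicalize: accept the tibble form or hrex output + window table.
as_window_samples <- function(all_samples) {
  if (!is_tibble(all_samples) ||
      !all(c("window", "alpha_ref", "kappa", "samples") %in% names(all_samples))) {
    abort(paste("`all_samples` must be a tibble with columns window,",
                "alpha_ref, kappa, cut, samples (see `window_samples()`)"))
  }
  if (!"cut" %in% names(all_samples)) all_samples$cut <- 0.25
  all_samples
}

#' Collect HREX output into WHAM input
#'
#' @param run an `"hrex_run"` whose recorded values are alpha samples.
#' @param windows the `"umbrella_windows"` table the run used.
#' @param cut equilibration fraction discarded per window.
#' @return a window-samples tibble for [wham_1d()].
#' @export
collect_samples <- function(run, windows, cut = 0.25) {
  dplyr::bind_rows(lapply(seq_len(nrow(windows)), function(i) {
    w <- window_at(windows, i)
    s <- run$samples$value[run$samples$window == i]
    window_samples(i, w$alpha, w$kappa, s, cut = cut)
  }))
}

#' One-dimensional WHAM
#'
#' Reconstructs the unbiased free-energy profile F(alpha) from harmonic-
#' bias window samples by the standard self-consistent weighted-histogram
#' iteration: with bin counts n_m, window sizes N_i and biases
#' u_i(alpha) = (kappa_i/2)(alpha - alpha_i)^2,
#'   p_m  = n_m / sum_i N_i exp((f_i - u_i(alpha_m)) / kT)
#'   f_i  = -kT log sum_m p_m exp(-u_i(alpha_m) / kT)
#' iterated until the largest change in any f_i is below `tol` (in kT).
#' The profile is -kT log p, minimum-shifted to zero. Standard errors are
#' filled in by [wham_error()].
#'
#' @param all_samples window-samples tibble (see [window_samples()],
#'   [collect_samples()]).
#' @param n_bins number of histogram bins over the sampled alpha range.
#'   The default 200 gives several bins per window spacing for a
#'   30-window layout.
#' @param kT thermal energy (energy units of kappa).
#' @param tol convergence tolerance on max |delta f_i| in kT.
#' @param max_iter maximum iterations.
#' @return an object of class `"fep"`: tibble with columns `alpha`,
#'   `free_energy`, `std_error` (NA until [wham_error()]), plus
#'   attributes `f_windows`, `kT`, `iterations`, `converged`.
#' @export
wham_1d <- function(all_samples, n_bins = 200, kT = 1, tol = 1e-8,
                    max_iter = 1e5) {
  ws <- as_window_samples(all_samples)
  n_win <- nrow(ws)
  samp <- lapply(seq_len(n_win), function(i) retained_samples(ws[i, ]))
  n_i <- lengths(samp)
  rng <- range(unlist(samp))
  if (diff(rng) <= 0) abort("all samples identical: no range to histogram")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  counts <- matrix(0, n_win, n_bins)
  for (i in seq_len(n_win)) {
    idx <- findInterval(samp[[i]], edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts[i, ] <- tabulate(idx, n_bins)
  }
  if (n_win > 1L) {
    ord <- order(ws$alpha_ref)
    for (k in seq_len(n_win - 1L)) {
      a <- counts[ord[k], ] > 0; b <- counts[ord[k + 1L], ] > 0
      if (!any(a & b)) {
        warn(sprintf("windows %d and %d share no occupied histogram bins",
                     ws$window[ord[k]], ws$window[ord[k + 1L]]))
      }
    }
  }
  n_m <- colSums(counts)
  occupied <- n_m > 0
  # reduced bias b[i, m] = u_i(alpha_m)/kT
  bias <- outer(seq_len(n_win), which(occupied), function(i, m) {
    0.5 * ws$kappa[i] * (centers[m] - ws$alpha_ref[i])^2 / kT
  })
  eb <- exp(-bias)
  nm_occ <- n_m[occupied]
  f <- numeric(n_win)   # f_i / kT
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- as.numeric(crossprod(eb, n_i * exp(f)))  # per occupied bin
    p <- nm_occ / denom
    f_new <- -log(as.numeric(eb %*% p))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
    if (iter >= max_iter) {
      abort(sprintf("WHAM did not converge in %d iterations (residual %.3g kT)",
                    as.integer(max_iter), delta))
    }
  }
  fe <- -kT * log(p)
  fe <- fe - min(fe)
  out <- tibble(alpha = centers[occupied], free_energy = fe,
                std_error = NA_real_)
  structure(out, f_windows = kT * f, kT = kT, iterations = iter,
            converged = TRUE, n_samples = sum(n_i),
            window_alpha = ws$alpha_ref, window_kappa = ws$kappa,
            class = c("fep", class(out)))
}

# Block-averaged standard error of the mean of a series: split into
# n_blocks contiguous blocks, sd of block means / sqrt(n_blocks).
# Insensitive to within-block correlation, unlike the naive sd/sqrt(n).
block_error <- function(x, n_blocks = 10L) {
  n <- length(x)
  if (n < 2L * n_blocks) n_blocks <- max(2L, n %/% 2L)
  if (n < 4L) abort("too few samples for block averaging (need >= 4)")
  cuts <- floor(seq(0, n, length.out = n_blocks + 1L))
  bm <- vapply(seq_len(n_blocks),
               function(k) mean(x[(cuts[k] + 1L):cuts[k + 1L]]), numeric(1))
  sd(bm) / sqrt(n_blocks)
}

#' Statistical errors of the free-energy profile
#'
#' Estimates the uncertainty of each window's mean sampled coordinate by
#' block averaging (correlation-aware), converts it to a mean-force
#' uncertainty kappa * se(mean alpha), propagates it across each
#' adjacent-window link by the trapezoid rule, and accumulates the link
#' variances in quadrature along the window chain. Errors are therefore
#' free-energy-difference errors relative to the first window and grow
#' monotonically with distance from it. Bin-level errors are interpolated
#' from the window-chain errors.
#'
#' @param all_samples the window-samples tibble used for [wham_1d()].
#' @param profile the `"fep"` returned by [wham_1d()].
#' @param n_blocks number of blocks for the block-average estimate.
#' @return the profile with `std_error` filled in; per-window errors in
#'   attribute `window_errors` (tibble: window, alpha_ref, mean_alpha,
#'   se_mean, cum_error).
#' @export
wham_error <- function(all_samples, profile, n_blocks = 10L) {
  ws <- as_window_samples(all_samples)
  if (nrow(ws) < 2L) abort("error propagation needs at least 2 windows")
  ord <- order(ws$alpha_ref)
  ws <- ws[ord, ]
  mean_a <- se_a <- numeric(nrow(ws))
  for (i in seq_len(nrow(ws))) {
    s <- retained_samples(ws[i, ])
    mean_a[i] <- mean(s)
    se_a[i] <- block_error(s, n_blocks)
  }
  se_force <- ws$kappa * se_a          # mean-force uncertainty per window
  d_alpha <- diff(ws$alpha_ref)
  var_link <- (d_alpha / 2)^2 * (se_force[-length(se_force)]^2 +
                                   se_force[-1]^2)
  cum_err <- sqrt(c(0, cumsum(var_link)))
  werr <- tibble(window = ws$window, alpha_ref = ws$alpha_ref,
                 mean_alpha = mean_a, se_mean = se_a, cum_error = cum_err)
  prof_err <- approx(ws$alpha_ref, cum_err, xout = profile$alpha,
                     rule = 2)$y
  profile$std_error <- prof_err
  attr(profile, "window_errors") <- werr
  profile
}

#' @export
print.fep <- function(x, ...) {
  cat(sprintf(
    "<fep> %d bin(s), kT = %g, F range [0, %.4g], WHAM converged in %d iteration(s)\n",
    nrow(x), attr(x, "kT"), max(x$free_energy), attr(x, "iterations")))
  NextMethod()
}

#' @method tidy fep
#' @export
tidy.fep <- function(x, ...) {
  tibble(alpha = x$alpha, free_energy = x$free_energy, std_error = x$std_error)
}

#' @method glance fep
#' @export
glance.fep <- function(x, ...) {
  tibble(
    n_bins = nrow(x), n_windows = length(attr(x, "f_windows")),
    n_samples = attr(x, "n_samples"), kT = attr(x, "kT"),
    iterations = attr(x, "iterations"), converged = isTRUE(attr(x, "converged")),
    barrier = max(x$free_energy),
    alpha_min = x$alpha[which.min(x$free_energy)]
  )
}

#' Plot a free-energy profile
#'
#' @param object a `"fep"` object.
#' @param ... unused.
#' @return a ggplot: F(alpha) with a shaded standard-error ribbon when
#'   errors are available.
#' @method autoplot fep
#' @export
autoplot.fep <- function(object, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$alpha,
                                                  y = .data$free_energy))
  if (any(is.finite(object$std_error))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$free_energy - .data$std_error,
                   ymax = .data$free_energy + .data$std_error),
      fill = "steelblue", alpha = 0.25)
  }
  p + ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = expression(alpha),
                  y = sprintf("free energy (kT = %g)", attr(object, "kT")))
}

# Local minima of a profile after light smoothing; used to characterize
# the overall shape (single valley vs multiple basins).
#' Count local minima of a profile after moving-average smoothing
#'
#' @param profile a `"fep"`.
#' @param smooth_kT smoothing scale: bins whose free-energy variation is
#'   below this are flattened by a moving average wide enough that
#'   fluctuations of that size do not create spurious minima.
#' @return integer positions (alpha) of the local minima.
#' @export
profile_minima <- function(profile, smooth_kT = 0.1) {
  f <- profile$free_energy
  kT <- attr(profile, "kT")
  if (is.null(kT)) kT <- 1
  thr <- smooth_kT * kT
  n <- length(f)
  # light moving-average smoothing (5-bin window)
  fs <- vapply(seq_len(n), function(i) {
    mean(f[max(1, i - 2L):min(n, i + 2L)])
  }, numeric(1))
  # strict-descent local minima (plateaus collapse to their first bin)
  cand <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1L) fs[i] < fs[i - 1L] else TRUE
    right <- if (i < n) fs[i] <= fs[i + 1L] else TRUE
    left && right
  }, logical(1)))
  if (length(cand) <= 1L) return(profile$alpha[cand])
  # persistence pruning: merge minima whose separating barrier is < thr
  repeat {
    merged <- FALSE
    for (k in seq_len(length(cand) - 1L)) {
      i <- cand[k]; j <- cand[k + 1L]
      barrier <- max(fs[i:j]) - max(fs[i], fs[j])
      if (barrier < thr) {
        cand <- cand[-(if (fs[i] <= fs[j]) k + 1L else k)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  profile$alpha[cand]
}
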