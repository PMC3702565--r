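#' Reduced energy change for a bias swap
#'
#' When two windows attempt to exchange their restraining potentials the
#' combined Hamiltonian changes by
#' Delta = [u_i(x_j) + u_j(x_i) - u_i(x_i) - u_j(x_j)] / kT.
#'
#' @param u_i,u_j bias potential functions (energy units).
#' @param x_i,x_j current configurations of the two windows.
#' @param kT thermal energy in the same units.
#' @return dimensionless Delta.
#' @export
swap_delta <- function(u_i, u_j, x_i, x_j, kT) {
  if (kT <= 0) abort("`kT` must be positive")
  (u_i(x_j) + u_j(x_i) - u_i(x_i) - u_j(x_j)) / kT
}

#' Metropolis decision for a swap attempt
#'
#' Accepted outright when Delta <= 0, otherwise with probability
#' exp(-Delta). Consumes one uniform draw from the current RNG stream
#' only when Delta > 0, so decisions are reproducible given the seed.
#'
#' @param delta dimensionless energy change from [swap_delta()].
#' @return logical: accept?
#' @export
attempt_swap <- function(delta) {
  if (delta <= 0) TRUE else runif(1) < exp(-delta)
}

# Deterministic per-(replica, cycle) sub-seed; keeps every propagation
# independent of how many RNG draws other replicas or the swap layer use,
# so a no-exchange run is bit-identical to independent umbrella sampling.
# Kept below 2^31.
sub_seed <- function(seed, replica, cycle) {
  (seed + 1000003 * replica + 7919 * cycle) %% 2147483587L
}

#' Hamiltonian replica exchange over umbrella windows
#'
#' Interleaves sampler propagation with Metropolis-accepted swaps of the
#' bias potentials between adjacent windows, alternating the (1,2),(3,4),
#' ... and (2,3),(4,5),... pairing phases. Swaps exchange bias
#' assignments rather than configurations (equivalent, cheaper
#' bookkeeping): each replica keeps its configuration and may change the
#' window it serves. Samples are recorded per window — the series WHAM
#' consumes — not per replica.
#'
#' @param propagate function `(x, bias, seed)` advancing a configuration
#'   for one exchange interval under the given bias; must use `seed` for
#'   all of its randomness.
#' @param x0 list of initial configurations, one per window.
#' @param biases list of bias potential functions `u_i(x)` (energy units).
#' @param n_cycles number of propagate/swap cycles.
#' @param kT thermal energy (kcal/mol for protein-facing runs; default
#'   0.5962, i.e. 300 K. Toy runs typically pass `kT = 1`).
#' @param record function `(x, window)` returning the scalar recorded for
#'   a window each cycle (default: the configuration's first component).
#' @param seed integer seed controlling the whole run.
#' @param exchange set `FALSE` to disable swaps (independent umbrella
#'   sampling with identical propagation streams).
#' @return an object of class `"hrex_run"`: list with `samples`
#'   (tibble: cycle, window, replica, value), `exchange_log` (tibble:
#'   cycle, window_i, window_j, delta, accepted), `acceptance_rate`,
#'   and `window_of_replica` (final assignment).
#' @export
run_hrex <- function(propagate, x0, biases, n_cycles, kT = KT_300K,
                     record = NULL, seed = 1L, exchange = TRUE) {
  n_win <- length(biases)
  if (n_win < 2L) abort("replica exchange needs at least 2 windows")
  if (length(x0) != n_win) abort("`x0` must supply one configuration per window")
  if (is.null(record)) record <- function(x, window) x[[1]]
  xs <- x0                      # configuration of each replica
  win_of <- seq_len(n_win)      # window currently served by each replica
  rep_of <- seq_len(n_win)      # inverse map
  val <- matrix(NA_real_, n_cycles, n_win)
  rep_rec <- matrix(NA_integer_, n_cycles, n_win)
  log_cycle <- integer(0); log_i <- integer(0); log_j <- integer(0)
  log_delta <- numeric(0); log_acc <- logical(0)
  swap_seed_state <- NULL
  for (cyc in seq_len(n_cycles)) {
    for (r in seq_len(n_win)) {
      xs[[r]] <- propagate(xs[[r]], biases[[win_of[r]]],
                           sub_seed(seed, r, cyc))
    }
    for (r in seq_len(n_win)) {
      w <- win_of[r]
      val[cyc, w] <- record(xs[[r]], w)
      rep_rec[cyc, w] <- r
    }
    if (exchange) {
      # dedicated RNG stream for swap decisions
      if (is.null(swap_seed_state)) {
        set.seed(seed %% 2147483587L)
      } else {
        assign(".Random.seed", swap_seed_state, envir = globalenv())
      }
      first <- if (cyc %% 2L == 1L) 1L else 2L
      i <- first
      while (i + 1L <= n_win) {
        ri <- rep_of[i]; rj <- rep_of[i + 1L]
        delta <- swap_delta(biases[[i]], biases[[i + 1L]], xs[[ri]], xs[[rj]], kT)
        acc <- attempt_swap(delta)
        log_cycle <- c(log_cycle, cyc); log_i <- c(log_i, i)
        log_j <- c(log_j, i + 1L); log_delta <- c(log_delta, delta)
        log_acc <- c(log_acc, acc)
        if (acc) {
          win_of[ri] <- i + 1L; win_of[rj] <- i
          rep_of[i] <- rj; rep_of[i + 1L] <- ri
        }
        i <- i + 2L
      }
      swap_seed_state <- get(".Random.seed", envir = globalenv())
    }
  }
  samples <- tibble(
    cycle = rep(seq_len(n_cycles), times = n_win),
    window = rep(seq_len(n_win), each = n_cycles),
    replica = as.integer(rep_rec[cbind(rep(seq_len(n_cycles), times = n_win),
                                       rep(seq_len(n_win), each = n_cycles))]),
    value = val[cbind(rep(seq_len(n_cycles), times = n_win),
                      rep(seq_len(n_win), each = n_cycles))]
  )
  exchange_log <- tibble(cycle = log_cycle, window_i = log_i, window_j = log_j,
                         delta = log_delta, accepted = log_acc)
  structure(
    list(samples = samples, exchange_log = exchange_log,
         acceptance_rate = if (nrow(exchange_log)) mean(exchange_log$accepted) else NA_real_,
         window_of_replica = win_of, final_states = xs),
    class = "hrex_run"
  )
}

#' @export
print.hrex_run <- function(x, ...) {
  cat(sprintf("<hrex_run> %d window(s), %d cycle(s), swap acceptance %.1f%%\n",
              length(x$window_of_replica), max(x$samples$cycle),
              100 * x$acceptance_rate))
  invisible(x)
}

#' Independent umbrella sampling (no exchange)
#'
#' Runs each window's sampler with the same per-(replica, cycle) seeding
#' as [run_hrex()] but no swap attempts; bit-identical to
#' `run_hrex(..., exchange = FALSE)`.
#'
#' @inheritParams run_hrex
#' @return same structure as [run_hrex()] (empty exchange log).
#' @export
run_umbrella <- function(propagate, x0, biases, n_cycles, record = NULL,
                         seed = 1L) {
  run_hrex(propagate, x0, biases, n_cycles, kT = 1, record = record,
           seed = seed, exchange = FALSE)
}
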