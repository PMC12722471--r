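# internal: unpack geometry/params into the C++ engine's argument list
engine_args <- function(geometry, params) {
  stopifnot(inherits(geometry, "ryr_geometry"), inherits(params, "ryr_params"))
  b <- geometry$bonds
  list(n_channels = nrow(geometry$channels),
       bond_a = as.integer(b$a - 1L), bond_i = as.integer(b$i - 1L),
       bond_b = as.integer(b$b - 1L), bond_j = as.integer(b$j - 1L),
       bond_sigma = as.numeric(b$sigma),
       delta = params$delta, kfo = params$kfo, kb = params$kb,
       g = params$g, co = params$co)
}

#' Simulate the waiting time to a spontaneous Ca spark
#'
#' Runs one exact Gillespie simulation of the coupled subunit lattice
#' from the all-closed state and returns the first-passage time `T` at
#' which the open-channel count first reaches `params$nc`. Event times
#' are exponential with the current total propensity; there is no time
#' discretization. If the threshold is not reached by `t_max` the run is
#' censored and the elapsed time is a lower bound on `T`.
#'
#' @param geometry An [ryr_geometry][cluster_geometry].
#' @param params An [ryr_params()] object.
#' @param t_max Censoring horizon, ms. Default 1e7.
#' @param seed Optional integer seed (calls `set.seed`).
#' @param record_trajectory Record `(time, n_open)` at every change of
#'   the open-channel count (memory stays bounded because subunit
#'   flickers that do not change `n_open` are not stored).
#' @param track_states For systems with at most 16 subunits, also return
#'   the time-weighted occupancy of every full subunit configuration
#'   (state code: bit `4(c-1)+(i-1)` set when subunit `i` of channel `c`
#'   is open).
#' @param max_events Stop after this many events (0 = unlimited); used
#'   for fixed-length occupancy sampling.
#' @param audit Rebuild and cross-check the incremental propensity sums
#'   every 4096 events (1e-9 relative tolerance); aborts on mismatch.
#' @return An object of class `ryr_fpt`: list with `T` (ms, `NA` if
#'   censored), `time`, `censored`, `n_events`, `n_open`, `seed`, and
#'   if requested `trajectory` (data.frame `time_ms`, `n_open`) and
#'   `state_time`.
#' @examples
#' g <- build_oblique(3, 3, sigma = 0.5)
#' p <- ryr_params(co = 20, nc = 2)
#' simulate_waiting_time(g, p, seed = 1)$T
#' @export
simulate_waiting_time <- function(geometry, params, t_max = 1e7,
                                  seed = NULL, record_trajectory = TRUE,
                                  track_states = FALSE, max_events = 0,
                                  audit = FALSE) {
  stopifnot(t_max > 0)
  if (!is.null(seed)) set.seed(seed)
  a <- engine_args(geometry, params)
  res <- ssa_run_cpp(a$n_channels, a$bond_a, a$bond_i, a$bond_b, a$bond_j,
                     a$bond_sigma, a$delta, a$kfo, a$kb, a$g, a$co,
                     params$nc, params$open_rule_min_subunits, t_max,
                     record_trajectory, track_states, max_events, audit)
  out <- list(T = res$T, time = res$time, censored = res$censored,
              n_events = res$n_events, n_open = res$n_open,
              seed = if (is.null(seed)) NA_integer_ else seed)
  if (record_trajectory)
    out$trajectory <- data.frame(time_ms = res$traj_t, n_open = res$traj_no)
  if (track_states) out$state_time <- res$state_time
  structure(out, class = "ryr_fpt")
}

#' @export
print.ryr_fpt <- function(x, ...) {
  if (x$censored)
    cat(sprintf("Censored run: n_open < nc up to t_max = %g ms (%g events)\n",
                x$time, x$n_events))
  else
    cat(sprintf("Spark waiting time T = %g ms (%g events)\n", x$T, x$n_events))
  invisible(x)
}

#' Empirical first-event statistics from the all-closed state
#'
#' Draws the first SSA event `n_reps` times (resetting to all-closed each
#' time): the exponential waiting time and which subunit flips. Used to
#' validate the event-timing and selection laws of the engine.
#'
#' @inheritParams simulate_waiting_time
#' @param n_reps Number of draws.
#' @return List with numeric `dt` (ms) and integer `subunit` (1-based
#'   global subunit index `4(c-1)+i`).
#' @export
first_event_sample <- function(geometry, params, n_reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- engine_args(geometry, params)
  res <- ssa_first_event_cpp(as.integer(n_reps), a$n_channels,
                             a$bond_a, a$bond_i, a$bond_b, a$bond_j,
                             a$bond_sigma, a$delta, a$kfo, a$kb, a$g, a$co,
                             params$open_rule_min_subunits)
  list(dt = res$dt, subunit = res$subunit + 1L)
}

#' Ensemble of independent spark waiting-time runs
#'
#' Runs `n_runs` independent first-passage simulations. Per-run seeds are
#' pre-drawn from the master seed, so the ensemble is bit-reproducible
#' and independent of execution order. When `geometry` is a function, a
#' fresh geometry is sampled per run (`geometry(geo_seed)`), matching the
#' ensemble protocols for diluted and grown clusters.
#'
#' The summary follows the 5x10 convention: `mean_T` is the arithmetic
#' mean over all runs, and `err_T` is the standard deviation of `k`
#' disjoint subset means of `m` runs each (defaults `k = 5`,
#' `m = n_runs / k`). Censored runs enter the mean at `t_max` and flag
#' the mean as a lower bound.
#'
#' @param geometry An [ryr_geometry][cluster_geometry], or a function of
#'   one integer seed returning one.
#' @param params [ryr_params()] object.
#' @param n_runs Number of independent runs (paper protocol: 50).
#' @param seed Master integer seed.
#' @param t_max Censoring horizon per run, ms.
#' @return An object of class `ryr_ensemble`: list with `times`,
#'   `censored`, `mean_T`, `err_T`, `n_censored`, `lower_bound`,
#'   `runs` (data.frame `run_id`, `seed`, `T_ms`, `censored`,
#'   `n_events`), `params`, `n_runs`, `seed`.
#' @export
run_ensemble <- function(geometry, params, n_runs = 50L, seed = 1L,
                         t_max = 1e7) {
  stopifnot(n_runs >= 1L)
  set.seed(seed)
  sim_seeds <- sample.int(2147483646L, n_runs)
  geo_seeds <- sample.int(2147483646L, n_runs)
  times <- numeric(n_runs)
  cens <- logical(n_runs)
  nev <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    g <- if (is.function(geometry)) geometry(geo_seeds[r]) else geometry
    res <- simulate_waiting_time(g, params, t_max = t_max,
                                 seed = sim_seeds[r],
                                 record_trajectory = FALSE)
    times[r] <- res$time
    cens[r] <- res$censored
    nev[r] <- res$n_events
  }
  summarize_ensemble(times, cens, nev, sim_seeds, params, seed)
}

summarize_ensemble <- function(times, cens, nev, sim_seeds, params, seed) {
  n_runs <- length(times)
  k <- min(5L, n_runs)
  m <- n_runs %/% k
  block_means <- vapply(seq_len(k), function(b)
    mean(times[((b - 1L) * m + 1L):(b * m)]), numeric(1))
  structure(list(
    times = times, censored = cens,
    mean_T = mean(times),
    err_T = if (k > 1L) sd(block_means) else NA_real_,
    n_censored = sum(cens),
    lower_bound = any(cens),
    runs = data.frame(run_id = seq_len(n_runs), seed = sim_seeds,
                      T_ms = times, censored = cens, n_events = nev),
    params = params, n_runs = n_runs, seed = seed),
    class = "ryr_ensemble")
}

#' @export
print.ryr_ensemble <- function(x, ...) {
  cat(sprintf("Spark waiting-time ensemble: %d runs, mean T = %.4g ms (err %.3g)%s\n",
              x$n_runs, x$mean_T, x$err_T,
              if (x$lower_bound)
                sprintf(" [lower bound: %d censored]", x$n_censored) else ""))
  invisible(x)
}
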