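# Parameter-sweep drivers over the spark waiting time, and result I/O.

new_sweep <- function(points, runs, spec) {
  structure(list(points = points, runs = runs, spec = spec),
            class = "ryr_sweep")
}

#' @export
print.ryr_sweep <- function(x, ...) {
  cat(sprintf("Spark waiting-time sweep over %s (%d points, %d runs/point):\n",
              x$spec$variable, nrow(x$points), x$spec$runs))
  print(x$points, row.names = FALSE)
  invisible(x)
}

# shared driver: one ensemble per point; geometry_for(point_value) returns
# either a static geometry or a per-run generator function(seed)
run_point_sweep <- function(variable, values, geometry_for, params_for,
                            runs, seed, t_max, spec_extra) {
  set.seed(seed)
  point_seeds <- sample.int(2147483646L, length(values))
  pts <- vector("list", length(values))
  run_tabs <- vector("list", length(values))
  for (k in seq_along(values)) {
    ens <- run_ensemble(geometry_for(values[k]), params_for(values[k]),
                        n_runs = runs, seed = point_seeds[k], t_max = t_max)
    pts[[k]] <- data.frame(sweep_value = values[k],
                           mean_T_ms = ens$mean_T,
                           err_T_ms = ens$err_T,
                           n_runs = ens$n_runs,
                           n_censored = ens$n_censored)
    run_tabs[[k]] <- cbind(sweep_value = values[k], ens$runs)
  }
  spec <- c(list(variable = variable, values = values, runs = runs,
                 seed = seed, t_max = t_max,
                 package_version = as.character(packageVersion("ryrcluster"))),
            spec_extra)
  new_sweep(do.call(rbind, pts), do.call(rbind, run_tabs), spec)
}

#' Sweep the diastolic Ca concentration
#'
#' Measures the mean spark waiting time at each background Ca
#' concentration for a full lattice of the given architecture, as in the
#' waiting-time-vs-Ca protocol (sizes 5x5 to 20x20, sigma 0 to 1, co
#' from 5 to 120 uM, 50 runs per point).
#'
#' @param co_values Ca concentrations to sweep, \eqn{\mu}M.
#' @param architecture `"oblique"` or `"adjoining"`.
#' @param size Lattice extents `c(nx, ny)`.
#' @param sigma Inter-channel coupling strength.
#' @param params Base [ryr_params()]; `co` is overridden per point.
#' @param runs Runs per point.
#' @param seed Master seed.
#' @param t_max Censoring horizon per run, ms.
#' @return An `ryr_sweep`: `points` (columns `sweep_value`, `mean_T_ms`,
#'   `err_T_ms`, `n_runs`, `n_censored`), per-run table `runs`, and the
#'   provenance `spec`.
#' @export
sweep_co <- function(co_values, architecture = c("oblique", "adjoining"),
                     size = c(10, 10), sigma = 0.5, params = ryr_params(),
                     runs = 50L, seed = 1L, t_max = 1e7) {
  architecture <- match.arg(architecture)
  geom <- build_architecture(architecture, size[1L], size[2L], sigma)
  run_point_sweep("co", co_values,
                  geometry_for = function(v) geom,
                  params_for = function(v) { params$co <- v; params },
                  runs, seed, t_max,
                  list(architecture = architecture, size = size,
                       sigma = sigma, params = unclass(params)))
}

#' Sweep the inter-channel coupling strength
#'
#' @param sigma_values Coupling strengths to sweep.
#' @param co Fixed Ca concentration, \eqn{\mu}M (protocol values: 5.0 at
#'   rest, 100 for the high-Ca regime).
#' @inheritParams sweep_co
#' @return An `ryr_sweep` (see [sweep_co()]).
#' @export
sweep_sigma <- function(sigma_values,
                        architecture = c("oblique", "adjoining"),
                        size = c(10, 10), co = 5, params = ryr_params(),
                        runs = 50L, seed = 1L, t_max = 1e7) {
  architecture <- match.arg(architecture)
  params$co <- co
  run_point_sweep("sigma", sigma_values,
                  geometry_for = function(v)
                    build_architecture(architecture, size[1L], size[2L], v),
                  params_for = function(v) params,
                  runs, seed, t_max,
                  list(architecture = architecture, size = size, co = co,
                       params = unclass(params)))
}

#' Sweep the bond-retention probability of a diluted cluster
#'
#' A fresh Bernoulli dilution mask is drawn for every run (an ensemble of
#' connectivity matrices per point), per the fragmentation protocol
#' (10x10 lattice, sigma = 1, co = 2 uM).
#'
#' @param p_values Bond-retention probabilities in \[0, 1\].
#' @inheritParams sweep_sigma
#' @return An `ryr_sweep` (see [sweep_co()]).
#' @export
sweep_dilution <- function(p_values,
                           architecture = c("adjoining", "oblique"),
                           size = c(10, 10), sigma = 1, co = 2,
                           params = ryr_params(), runs = 50L, seed = 1L,
                           t_max = 1e7) {
  architecture <- match.arg(architecture)
  params$co <- co
  base <- build_architecture(architecture, size[1L], size[2L], sigma)
  run_point_sweep("p", p_values,
                  geometry_for = function(v)
                    function(s) dilute_bonds(base, v, seed = s),
                  params_for = function(v) params,
                  runs, seed, t_max,
                  list(architecture = architecture, size = size,
                       sigma = sigma, co = co, params = unclass(params)))
}

#' Sweep the clustering exponent of grown morphologies
#'
#' A fresh preferential-attachment morphology is grown for every run and
#' its adjacent channels bonded with the oblique pattern (protocol: 50
#' channels on a 20x20 lattice, co = 2.5 uM).
#'
#' @param alpha_values Clustering exponents \eqn{\alpha \ge 0}.
#' @param n_channels Channels per grown cluster.
#' @param grid Lattice extents `c(nx, ny)` for growth.
#' @inheritParams sweep_sigma
#' @return An `ryr_sweep` (see [sweep_co()]).
#' @export
sweep_alpha <- function(alpha_values, n_channels = 50L, grid = c(20, 20),
                        sigma = 1, co = 2.5, params = ryr_params(),
                        runs = 50L, seed = 1L, t_max = 1e7) {
  params$co <- co
  run_point_sweep("alpha", alpha_values,
                  geometry_for = function(v)
                    function(s) grow_preferential(n_channels, grid[1L],
                                                  grid[2L], v, sigma,
                                                  seed = s),
                  params_for = function(v) params,
                  runs, seed, t_max,
                  list(n_channels = n_channels, grid = grid, sigma = sigma,
                       co = co, params = unclass(params)))
}

build_architecture <- function(architecture, nx, ny, sigma) {
  switch(architecture,
         adjoining = build_adjoining(nx, ny, sigma),
         oblique = build_oblique(nx, ny, sigma),
         stop("unknown architecture: ", architecture))
}

#' Write / load sweep results
#'
#' Writes `points.csv` (per-point summary), `runs.csv` (per-run table)
#' and `provenance.json` (the sweep spec: variable, values, seeds,
#' package version) into a directory, and loads them back as an
#' `ryr_sweep`. The provenance is sufficient to replay the sweep.
#'
#' @param sweep An `ryr_sweep`.
#' @param dir Output directory (created if missing).
#' @return `write_results` returns `dir` invisibly; `load_results`
#'   returns an `ryr_sweep`.
#' @export
write_results <- function(sweep, dir) {
  stopifnot(inherits(sweep, "ryr_sweep"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sweep$points, file.path(dir, "points.csv"), row.names = FALSE)
  write.csv(sweep$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  jsonlite::write_json(sweep$spec, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_results
#' @export
load_results <- function(dir) {
  for (f in c("points.csv", "runs.csv", "provenance.json"))
    if (!file.exists(file.path(dir, f)))
      stop("missing results file: ", file.path(dir, f))
  points <- read.csv(file.path(dir, "points.csv"))
  need <- c("sweep_value", "mean_T_ms", "err_T_ms", "n_runs", "n_censored")
  if (!all(need %in% names(points)))
    stop("points.csv lacks required columns: ",
         paste(setdiff(need, names(points)), collapse = ", "))
  runs <- read.csv(file.path(dir, "runs.csv"))
  spec <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  new_sweep(points, runs, spec)
}

#' Replay a sweep from its provenance record
#'
#' Re-runs the sweep described by a provenance spec (as produced by the
#' `sweep_*` functions and stored by [write_results()]); with the same
#' package version this reproduces the stored tables exactly.
#'
#' @param spec A sweep provenance spec (the `spec` element of an
#'   `ryr_sweep`).
#' @return A freshly computed `ryr_sweep`.
#' @export
replay_sweep <- function(spec) {
  pars <- do.call(ryr_params, spec$params)
  common <- list(runs = spec$runs, seed = spec$seed, t_max = spec$t_max,
                 params = pars)
  switch(spec$variable,
    co = do.call(sweep_co, c(list(co_values = spec$values,
                                  architecture = spec$architecture,
                                  size = spec$size, sigma = spec$sigma),
                             common)),
    sigma = do.call(sweep_sigma, c(list(sigma_values = spec$values,
                                        architecture = spec$architecture,
                                        size = spec$size, co = spec$co),
                                   common)),
    p = do.call(sweep_dilution, c(list(p_values = spec$values,
                                       architecture = spec$architecture,
                                       size = spec$size, sigma = spec$sigma,
                                       co = spec$co),
                                  common)),
    alpha = do.call(sweep_alpha, c(list(alpha_values = spec$values,
                                        n_channels = spec$n_channels,
                                        grid = spec$grid, sigma = spec$sigma,
                                        co = spec$co),
                                   common)),
    stop("unknown sweep variable: ", spec$variable))
}
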