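#' Kinetic and coupling parameters of the RyR2 cluster model
#'
#' Bundles every rate and coupling constant of the tetramer gating model.
#' Units are fixed package-wide: time in ms, concentration in \eqn{\mu}M,
#' rates in ms\eqn{^{-1}}.
#'
#' The model: each RyR2 channel is four two-state subunits
#' (\eqn{s_i = \pm 1}) on a ring. A closed subunit opens at rate
#' \eqn{k_f \gamma_i} with \eqn{k_f = k_{fo} \cdot Ca}, and an open subunit
#' closes at rate \eqn{k_b / \gamma_i}, where
#' \eqn{\gamma_i = \exp[\delta (s_{i-1} + s_{i+1}) + \sum_b \sigma_b s_b]}
#' collects the ring neighbours and any inter-channel contact subunits
#' \eqn{s_b}. The dyadic calcium concentration is
#' \eqn{Ca = c_o + g \, n_o}, with \eqn{n_o} the number of conducting
#' channels (those with at least `open_rule_min_subunits` open subunits).
#'
#' @param delta Dimensionless intra-channel conformational-mismatch
#'   penalty \eqn{\delta} (the product of inverse temperature and the
#'   interface energy). Default 0.5.
#' @param sigma Dimensionless inter-channel coupling strength \eqn{\sigma}
#'   relative to the intra-channel coupling; geometry builders take a
#'   `sigma` argument and store it per bond, so this field is the default
#'   used when a geometry is built from a parameter set. Default 1.
#' @param kfo Ca-binding rate constant, \eqn{\mu}M\eqn{^{-1}}ms\eqn{^{-1}}.
#'   Default 0.005.
#' @param kb Subunit closing base rate, ms\eqn{^{-1}}. Default 0.3
#'   (mean subunit open time about 3 ms).
#' @param g Dyadic Ca increment per open channel, \eqn{\mu}M. Default 25,
#'   so that 1-3 open channels give 25-75 \eqn{\mu}M.
#' @param co Background (diastolic) Ca concentration in the dyad,
#'   \eqn{\mu}M. Default 0.1.
#' @param nc Spark-detection threshold: a spark is declared when the
#'   open-channel count first reaches `nc`. Default 5.
#' @param open_rule_min_subunits Number of open subunits required for a
#'   channel to conduct (majority rule). Default 3.
#'
#' @return An object of class `ryr_params`: a named list of the validated
#'   fields above.
#' @examples
#' p <- ryr_params()
#' p$kfo * 100  # opening base rate at Ca = 100 uM
#' @export
ryr_params <- function(delta = 0.5, sigma = 1, kfo = 0.005, kb = 0.3,
                       g = 25, co = 0.1, nc = 5L,
                       open_rule_min_subunits = 3L) {
  p <- list(delta = as.numeric(delta), sigma = as.numeric(sigma),
            kfo = as.numeric(kfo), kb = as.numeric(kb),
            g = as.numeric(g), co = as.numeric(co), nc = as.integer(nc),
            open_rule_min_subunits = as.integer(open_rule_min_subunits))
  validate_params(p)
  structure(p, class = "ryr_params")
}

validate_params <- function(p) {
  num1 <- function(x) length(x) == 1L && is.finite(x)
  stopifnot(
    "delta must be a single finite number >= 0" = num1(p$delta) && p$delta >= 0,
    "sigma must be a single finite number >= 0" = num1(p$sigma) && p$sigma >= 0,
    "kfo must be > 0" = num1(p$kfo) && p$kfo > 0,
    "kb must be > 0" = num1(p$kb) && p$kb > 0,
    "g must be >= 0" = num1(p$g) && p$g >= 0,
    "co must be > 0" = num1(p$co) && p$co > 0,
    "nc must be an integer >= 1" = num1(p$nc) && p$nc >= 1L,
    "open_rule_min_subunits must be in 1..4" =
      num1(p$open_rule_min_subunits) &&
      p$open_rule_min_subunits >= 1L && p$open_rule_min_subunits <= 4L
  )
  invisible(p)
}

#' @export
print.ryr_params <- function(x, ...) {
  cat("RyR2 gating parameters (time ms, concentration uM):\n")
  cat(sprintf("  delta = %g, sigma = %g\n", x$delta, x$sigma))
  cat(sprintf("  kfo = %g /uM/ms, kb = %g /ms\n", x$kfo, x$kb))
  cat(sprintf("  g = %g uM per open channel, co = %g uM\n", x$g, x$co))
  cat(sprintf("  spark threshold nc = %d, conduction rule: >= %d of 4 subunits open\n",
              x$nc, x$open_rule_min_subunits))
  invisible(x)
}

#' Read / write a parameter set as flat JSON
#'
#' The file is a single flat JSON object whose keys are exactly the fields
#' of [ryr_params()]. Unknown keys are an error, so a misspelled field can
#' never be silently ignored.
#'
#' @param params An `ryr_params` object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   an `ryr_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "ryr_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(ryr_params))
  extra <- setdiff(names(x), known)
  if (length(extra) > 0L)
    stop("unknown parameter field(s) in ", path, ": ",
         paste(extra, collapse = ", "))
  do.call(ryr_params, x)
}
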