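# Brute-force continuous-time Markov-chain companion to the SSA engine.
#
# States are all 2^(4n) subunit configurations of an n-channel cluster,
# encoded as integers with bit 4(c-1)+(i-1) set when subunit i of channel
# c is open. Rates are recomputed here directly from the rate law (not
# via transition_rates or the C++ engine), so the oracle is an
# independent code path.

popcount4 <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L,
               3L, 4L)  # popcount of 0..15

# Build the full generator matrix (sparse) plus state metadata.
# fixed_ca overrides the Ca feedback (used for stationary analysis).
oracle_generator <- function(geometry, params, fixed_ca = NULL) {
  n <- nrow(geometry$channels)
  nsub <- 4L * n
  if (nsub > 16L)
    stop("exact oracle is limited to 16 subunits (4 channels)")
  ns <- bitwShiftL(1L, nsub)
  states <- 0:(ns - 1L)

  spin <- matrix(0, ns, nsub)
  for (u in seq_len(nsub))
    spin[, u] <- ifelse(bitwAnd(states, bitwShiftL(1L, u - 1L)) != 0L, 1, -1)

  open_per_channel <- matrix(0L, ns, n)
  for (c0 in seq_len(n)) {
    nib <- bitwAnd(bitwShiftR(states, 4L * (c0 - 1L)), 15L)
    open_per_channel[, c0] <- popcount4[nib + 1L]
  }
  n_open <- rowSums(open_per_channel >= params$open_rule_min_subunits)
  ca <- if (is.null(fixed_ca)) params$co + params$g * n_open else
    rep(fixed_ca, ns)

  # exponent e_u(state) = delta * (ring sum) + sum sigma * partner
  ex <- matrix(0, ns, nsub)
  for (u in seq_len(nsub)) {
    c0 <- ((u - 1L) %/% 4L) + 1L
    i <- ((u - 1L) %% 4L) + 1L
    rn <- ring_neighbors(i)
    acc <- params$delta *
      (spin[, (c0 - 1L) * 4L + rn[1L]] + spin[, (c0 - 1L) * 4L + rn[2L]])
    b <- geometry$bonds
    if (nrow(b) > 0L) {
      hit_a <- which(b$a == c0 & b$i == i)
      for (r in hit_a)
        acc <- acc + b$sigma[r] * spin[, (b$b[r] - 1L) * 4L + b$j[r]]
      hit_b <- which(b$b == c0 & b$j == i)
      for (r in hit_b)
        acc <- acc + b$sigma[r] * spin[, (b$a[r] - 1L) * 4L + b$i[r]]
    }
    ex[, u] <- acc
  }

  rate <- matrix(0, ns, nsub)
  targ <- matrix(0L, ns, nsub)
  for (u in seq_len(nsub)) {
    rate[, u] <- ifelse(spin[, u] < 0,
                        params$kfo * ca * exp(ex[, u]),
                        params$kb * exp(-ex[, u]))
    targ[, u] <- bitwXor(states, bitwShiftL(1L, u - 1L))
  }

  Q <- Matrix::sparseMatrix(i = rep(states + 1L, nsub),
                            j = as.vector(targ) + 1L,
                            x = as.vector(rate), dims = c(ns, ns))
  Q <- Q + Matrix::Diagonal(ns, -Matrix::rowSums(Q))
  list(Q = Q, n_open = n_open, ca = ca, states = states, n_states = ns)
}

# Solve A x = b for a sparse square system. Small systems go through the
# direct sparse LU; larger ones (the 4-channel state space is 65,536
# states, where LU fill-in is prohibitive) use Jacobi-scaled BiCGSTAB.
# The state graph is a hypercube, for which the Krylov iteration
# converges in a few dozen matrix products.
solve_sparse <- function(A, b, tol = 1e-12, max_iter = 10000L) {
  n <- nrow(A)
  if (n <= 4096L) return(as.numeric(Matrix::solve(A, b)))
  D <- Matrix::diag(A)
  As <- A / D
  bs <- b / D
  bnorm <- sqrt(sum(bs^2))
  x <- numeric(n)
  r <- bs - as.numeric(As %*% x)
  rh <- r
  rho <- alpha <- omega <- 1
  v <- p <- numeric(n)
  for (it in seq_len(max_iter)) {
    rho1 <- sum(rh * r)
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    v <- as.numeric(As %*% p)
    alpha <- rho / sum(rh * v)
    s <- r - alpha * v
    tt <- as.numeric(As %*% s)
    omega <- sum(tt * s) / sum(tt * tt)
    x <- x + alpha * p + omega * s
    r <- s - omega * tt
    if (sqrt(sum(r^2)) < tol * bnorm) return(x)
  }
  stop("iterative sparse solve failed to converge")
}

#' Exact mean first-passage time to spark threshold
#'
#' Enumerates all \eqn{2^{4n}} subunit configurations of a small cluster
#' (at most 4 channels), builds the exact generator of the
#' Ca-feedback-coupled chain, and solves the linear system for the mean
#' absorption time into the set of states with `n_open >= params$nc`.
#' This is the deterministic reference value for the mean spark waiting
#' time measured by [simulate_waiting_time()].
#'
#' @param geometry [ryr_geometry][cluster_geometry] with at most 4
#'   channels.
#' @param params [ryr_params()] object.
#' @return Expected time (ms) from the all-closed state to absorption;
#'   `Inf` if no state reaches the threshold.
#' @examples
#' g <- build_oblique(1, 1)
#' exact_mfpt(g, ryr_params(co = 60, delta = 0, g = 0, nc = 1))
#' @export
exact_mfpt <- function(geometry, params) {
  stopifnot(inherits(params, "ryr_params"))
  gen <- oracle_generator(geometry, params)
  absorbing <- gen$n_open >= params$nc
  if (absorbing[1L]) return(0)    # all-closed state already at threshold
  if (!any(absorbing)) return(Inf)
  trans <- which(!absorbing)
  tau <- solve_sparse(gen$Q[trans, trans, drop = FALSE],
                      rep(-1, length(trans)))
  as.numeric(tau[match(1L, trans)])
}

#' Exact stationary distribution at fixed Ca
#'
#' For `g = 0` the chain has no feedback, is irreducible, and satisfies
#' detailed balance; this solves the global balance equations exactly.
#' The resulting distribution is the Boltzmann measure implied by the
#' rate ratios (each subunit flip satisfies
#' \eqn{k_+ / k_- = (k_{fo} Ca / k_b) \gamma^2}).
#'
#' @param geometry [ryr_geometry][cluster_geometry] with at most 4
#'   channels.
#' @param params [ryr_params()] with `g = 0` (enforced; the feedback
#'   chain is absorbing-analysed only, via [exact_mfpt()]).
#' @return Numeric probability vector over all state codes
#'   `0:(2^(4n)-1)` (code bit `4(c-1)+(i-1)` = subunit `i` of channel `c`
#'   open), summing to 1.
#' @export
stationary_distribution <- function(geometry, params) {
  stopifnot(inherits(params, "ryr_params"))
  if (params$g != 0)
    stop("stationary_distribution requires g = 0 (fixed Ca)")
  gen <- oracle_generator(geometry, params, fixed_ca = params$co)
  ns <- gen$n_states
  A <- Matrix::t(gen$Q)
  A[1L, ] <- 1            # replace one balance equation by normalization
  b <- c(1, rep(0, ns - 1L))
  p <- solve_sparse(A, b)
  setNames(p, gen$states)
}
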