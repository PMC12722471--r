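#' Cooperative coupling factor of a subunit
#'
#' Computes \eqn{\gamma_i = \exp[\delta n_i + \sum_b \sigma_b s_b]},
#' where \eqn{n_i = s_{i-1} + s_{i+1}} is the sum of the two ring
#' neighbours of the subunit within its own tetramer and the sum runs
#' over the subunit's inter-channel contact partners (state \eqn{s_b},
#' strength \eqn{\sigma_b}). \eqn{\sigma_b} is itself a dimensionless
#' energy scale (like \eqn{\delta}), entering the exponent directly; a
#' subunit with no partners (cluster edge, broken bond) simply
#' contributes nothing to the exponent.
#'
#' @param intra_neighbor_sum Sum of the two ring neighbours' states, one
#'   of -2, 0, +2.
#' @param partner_states States (\eqn{\pm 1}) of inter-channel contact
#'   partners; may be empty.
#' @param partner_sigmas Coupling strength of each partner bond; recycled
#'   to the length of `partner_states` if scalar.
#' @param delta Mismatch penalty \eqn{\delta \ge 0}.
#' @return The (strictly positive) factor \eqn{\gamma_i}.
#' @examples
#' coupling_factor(-2, delta = 0.5)                    # exp(-1)
#' coupling_factor(-2, c(-1, -1), 1, delta = 0.5)      # exp(-3)
#' @export
coupling_factor <- function(intra_neighbor_sum, partner_states = numeric(),
                            partner_sigmas = numeric(), delta = 0.5) {
  stopifnot(is.finite(intra_neighbor_sum),
            intra_neighbor_sum %in% c(-2, 0, 2),
            is.finite(delta), delta >= 0)
  if (length(partner_states) > 0L) {
    stopifnot(all(is.finite(partner_states)),
              all(partner_states %in% c(-1, 1)),
              all(is.finite(partner_sigmas)))
    if (length(partner_sigmas) == 1L)
      partner_sigmas <- rep(partner_sigmas, length(partner_states))
    stopifnot(length(partner_sigmas) == length(partner_states))
    inter <- sum(partner_sigmas * partner_states)
  } else {
    inter <- 0
  }
  exp(delta * intra_neighbor_sum + inter)
}

# ring neighbours of subunit i in the 1-2-3-4-1 ring
ring_neighbors <- function(i) {
  c(if (i == 1L) 4L else i - 1L, if (i == 4L) 1L else i + 1L)
}

#' A lattice state: one \eqn{\pm 1} value per subunit of every channel
#'
#' Thin container validating the state matrix and caching the derived
#' quantities: the conducting-channel count and the dyadic Ca implied by
#' the rapid-diffusion approximation.
#'
#' @param s Integer matrix, one row per channel, 4 columns (subunits in
#'   ring order 1-2-3-4), entries -1 (closed) or +1 (open).
#' @param params An [ryr_params()] object.
#' @return An object of class `ryr_state`: list with elements `s`,
#'   `n_open` and `ca` (\eqn{\mu}M).
#' @export
lattice_state <- function(s, params) {
  stopifnot(is.matrix(s), ncol(s) == 4L, all(s %in% c(-1L, 1L)))
  n_open <- count_open_channels(s, params)
  structure(list(s = s, n_open = n_open,
                 ca = local_calcium(n_open, params)),
            class = "ryr_state")
}

#' Number of conducting channels in a state
#'
#' A channel conducts when at least `params$open_rule_min_subunits`
#' (default 3, the majority rule) of its four subunits are open. The
#' returned count is the \eqn{n_o} entering the dyadic Ca relation.
#'
#' @param state An `ryr_state` or a channels x 4 matrix of \eqn{\pm 1}.
#' @param params An [ryr_params()] object.
#' @return Non-negative integer count.
#' @export
count_open_channels <- function(state, params = ryr_params()) {
  s <- if (inherits(state, "ryr_state")) state$s else state
  stopifnot(is.matrix(s), ncol(s) == 4L, all(s %in% c(-1L, 1L)))
  sum(rowSums(s == 1L) >= params$open_rule_min_subunits)
}

#' Dyadic Ca under the rapid-diffusion approximation
#'
#' \eqn{Ca = c_o + g \, n_o}: Ca released by the open channels is assumed
#' uniform across the dyadic cleft because the Ca diffusion length over a
#' channel open time exceeds the cluster size (see [diffusion_length()]).
#'
#' @param n_open Number of conducting channels, \eqn{n_o \ge 0}.
#' @param params An [ryr_params()] object supplying `co` and `g`.
#' @return Local Ca concentration, \eqn{\mu}M.
#' @examples
#' local_calcium(3, ryr_params(co = 0.1))  # 75.1 uM
#' @export
local_calcium <- function(n_open, params = ryr_params()) {
  stopifnot(is.finite(n_open), n_open >= 0)
  params$co + params$g * n_open
}

#' Opening and closing rate of one subunit
#'
#' Evaluates the thermodynamically consistent rate pair
#' \eqn{k_{-1 \to +1} = k_{fo} Ca \, \gamma_i} (closed subunit) and
#' \eqn{k_{+1 \to -1} = k_b / \gamma_i} (open subunit) for the addressed
#' subunit, with \eqn{\gamma_i} from [coupling_factor()] using the
#' subunit's ring neighbours and its inter-channel bond partners from the
#' geometry. Exactly one of the two returned rates is nonzero: a closed
#' subunit cannot close, an open one cannot open. The ratio of the
#' opening rate (from the closed state) to the closing rate (from the
#' open state, same neighbours) is \eqn{(k_{fo} Ca / k_b)\gamma_i^2},
#' i.e. the chain satisfies detailed balance at fixed Ca.
#'
#' @param state `ryr_state` or channels x 4 matrix of \eqn{\pm 1}.
#' @param channel Channel index (row of the state matrix).
#' @param subunit Subunit index, 1..4.
#' @param params [ryr_params()] object.
#' @param geometry [ryr_geometry] supplying the inter-channel bonds; a
#'   `NULL` geometry means an isolated tetramer.
#' @return Named numeric vector `c(opening = ..., closing = ...)` in
#'   ms\eqn{^{-1}}.
#' @export
transition_rates <- function(state, channel, subunit, params,
                             geometry = NULL) {
  s <- if (inherits(state, "ryr_state")) state$s else state
  stopifnot(is.matrix(s), ncol(s) == 4L,
            channel >= 1L, channel <= nrow(s),
            subunit %in% 1:4)
  ca <- local_calcium(count_open_channels(s, params), params)
  rn <- ring_neighbors(subunit)
  intra <- s[channel, rn[1L]] + s[channel, rn[2L]]
  pstates <- numeric(); psigmas <- numeric()
  if (!is.null(geometry) && nrow(geometry$bonds) > 0L) {
    b <- geometry$bonds
    hit_a <- b$a == channel & b$i == subunit
    hit_b <- b$b == channel & b$j == subunit
    if (any(hit_a)) {
      pstates <- c(pstates, s[cbind(b$b[hit_a], b$j[hit_a])])
      psigmas <- c(psigmas, b$sigma[hit_a])
    }
    if (any(hit_b)) {
      pstates <- c(pstates, s[cbind(b$a[hit_b], b$i[hit_b])])
      psigmas <- c(psigmas, b$sigma[hit_b])
    }
  }
  gam <- coupling_factor(intra, pstates, psigmas, params$delta)
  if (s[channel, subunit] == -1L) {
    c(opening = params$kfo * ca * gam, closing = 0)
  } else {
    c(opening = 0, closing = params$kb / gam)
  }
}

#' Ca diffusion length over a channel open time
#'
#' \eqn{d = \sqrt{4 D \tau}}, returned in nm. With an effective cytosolic
#' diffusion coefficient of 100-250 \eqn{\mu}m\eqn{^2}/s and an open time
#' of about 1 ms this gives 600-1000 nm, which exceeds the diameter of
#' even the largest RyR2 clusters (about 400 nm) and justifies treating
#' the dyadic Ca pool as well mixed.
#'
#' @param D Effective diffusion coefficient, \eqn{\mu}m\eqn{^2}/s.
#' @param tau Time window (channel open time), ms.
#' @return Diffusion length in nm.
#' @examples
#' diffusion_length(100, 1)  # ~632 nm
#' @export
diffusion_length <- function(D, tau) {
  stopifnot(is.finite(D), D > 0, is.finite(tau), tau >= 0)
  # D um^2/s * tau ms -> um^2: D * tau/1000; sqrt -> um; *1000 -> nm
  sqrt(4 * D * tau / 1000) * 1000
}
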