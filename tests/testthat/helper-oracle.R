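# Independent brute-force CTMC construction used to cross-check the
# package's sparse oracle. Written with plain loops and explicit rate
# formulas on purpose: it shares no code with R/oracle.R or the C++
# engine. Practical up to 2 channels (256 states).

dense_generator <- function(geometry, params, fixed_ca = NULL) {
  n <- nrow(geometry$channels)
  nsub <- 4L * n
  ns <- 2L^nsub
  Q <- matrix(0, ns, ns)
  for (st in 0:(ns - 1L)) {
    bits <- as.integer(intToBits(st))[1:nsub]
    s <- ifelse(bits == 1L, 1, -1)
    sm <- matrix(s, ncol = 4L, byrow = TRUE)
    nopen <- sum(rowSums(sm == 1) >= params$open_rule_min_subunits)
    ca <- if (is.null(fixed_ca)) params$co + params$g * nopen else fixed_ca
    for (u in 1:nsub) {
      c0 <- (u - 1L) %/% 4L + 1L
      i <- (u - 1L) %% 4L + 1L
      im <- if (i == 1L) 4L else i - 1L
      ip <- if (i == 4L) 1L else i + 1L
      ee <- params$delta * (sm[c0, im] + sm[c0, ip])
      bb <- geometry$bonds
      if (nrow(bb) > 0L) for (r in seq_len(nrow(bb))) {
        if (bb$a[r] == c0 && bb$i[r] == i)
          ee <- ee + bb$sigma[r] * sm[bb$b[r], bb$j[r]]
        if (bb$b[r] == c0 && bb$j[r] == i)
          ee <- ee + bb$sigma[r] * sm[bb$a[r], bb$i[r]]
      }
      rate <- if (s[u] < 0) params$kfo * ca * exp(ee) else
        params$kb * exp(-ee)
      Q[st + 1L, bitwXor(st, bitwShiftL(1L, u - 1L)) + 1L] <- rate
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

dense_n_open <- function(n_channels, params) {
  nsub <- 4L * n_channels
  vapply(0:(2L^nsub - 1L), function(st) {
    bits <- as.integer(intToBits(st))[1:nsub]
    sm <- matrix(ifelse(bits == 1L, 1, -1), ncol = 4L, byrow = TRUE)
    sum(rowSums(sm == 1) >= params$open_rule_min_subunits)
  }, integer(1))
}

dense_mfpt <- function(geometry, params) {
  Q <- dense_generator(geometry, params)
  nopen <- dense_n_open(nrow(geometry$channels), params)
  absorbing <- nopen >= params$nc
  if (absorbing[1L]) return(0)
  if (!any(absorbing)) return(Inf)
  trans <- which(!absorbing)
  tau <- solve(Q[trans, trans, drop = FALSE], rep(-1, length(trans)))
  tau[match(1L, trans)]
}

# subunit-open count per state code, for grouping stationary masses
subunits_open_per_state <- function(n_subunits) {
  vapply(0:(2L^n_subunits - 1L), function(st)
    sum(as.integer(intToBits(st))[1:n_subunits]), integer(1))
}
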