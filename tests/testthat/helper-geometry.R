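# Brute-force count of von-Neumann-adjacent occupied pairs, used as the
# enumeration oracle for bond-count formulas.
brute_adjacent_pairs <- function(coords) {
  n <- nrow(coords)
  cnt <- 0L
  if (n < 2L) return(0L)
  for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
    if (abs(coords[a, 1L] - coords[b, 1L]) +
        abs(coords[a, 2L] - coords[b, 2L]) == 1L)
      cnt <- cnt + 1L
  }
  cnt
}
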