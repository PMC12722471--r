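test_that("coupling factor matches hand-evaluated values and limits", {
  # both ring neighbours closed, no partners
  expect_equal(coupling_factor(-2, delta = 0.5), exp(-1), tolerance = 1e-12)
  # uncoupled limit with no partners
  for (ni in c(-2, 0, 2)) expect_equal(coupling_factor(ni, delta = 0), 1.0)
  # two closed partners at sigma = 1 add -2 to the exponent directly
  expect_equal(coupling_factor(-2, c(-1, -1), 1, delta = 0.5), exp(-3),
               tolerance = 1e-12)
  # monotone increasing in a partner's state
  expect_gt(coupling_factor(0, 1, 0.7), coupling_factor(0, -1, 0.7))
  # scalar sigma recycles over partners
  expect_equal(coupling_factor(2, c(1, -1), 0.5, delta = 0.25),
               exp(0.5 + 0.5 - 0.5))
  expect_error(coupling_factor(-1, delta = 0.5))   # invalid neighbour sum
  expect_error(coupling_factor(-2, delta = NaN))
})

test_that("transition rates follow the k_f*gamma / k_b/gamma law", {
  p <- ryr_params(co = 100)
  s <- matrix(-1L, 1, 4)
  r <- transition_rates(s, 1, 1, p)
  expect_equal(unname(r["opening"]), 0.005 * 100 * exp(-1), tolerance = 1e-12)
  expect_equal(unname(r["closing"]), 0)

  # open subunit flanked by open ring neighbours: gamma = e, closing kb/e
  s2 <- matrix(c(1L, 1L, -1L, 1L), 1, 4)   # subunit 1 open, neighbours 2,4 open
  p0 <- ryr_params(co = 100, g = 0)
  r2 <- transition_rates(s2, 1, 1, p0)
  expect_equal(unname(r2["closing"]), 0.3 * exp(-1), tolerance = 1e-12)
  expect_equal(unname(r2["opening"]), 0)

  # symmetric uncoupled point: kfo*co = kb at co = 60 when delta = 0
  psym <- ryr_params(co = 60, delta = 0, g = 0)
  for (i in 1:4)
    expect_equal(unname(transition_rates(s, 1, i, psym)["opening"]), 0.3)
})

test_that("exactly one rate is nonzero and detailed balance holds at fixed Ca", {
  geom <- build_oblique(2, 2, sigma = 0.8)
  p <- ryr_params(co = 15, g = 0)   # g = 0: fixed Ca, reversible chain
  set.seed(101)
  for (rep in 1:25) {
    s <- matrix(sample(c(-1L, 1L), 16, replace = TRUE), 4, 4)
    ch <- sample(4, 1)
    su <- sample(4, 1)
    r <- transition_rates(s, ch, su, p, geom)
    expect_equal(sum(r > 0), 1L)
    # flip the subunit: ratio of opening (closed state) to closing (open
    # state, same neighbours) must be (kfo*Ca/kb) * gamma^2
    s_closed <- s; s_closed[ch, su] <- -1L
    s_open <- s; s_open[ch, su] <- 1L
    up <- transition_rates(s_closed, ch, su, p, geom)["opening"]
    dn <- transition_rates(s_open, ch, su, p, geom)["closing"]
    gam <- p$kb / dn                  # gamma recovered from closing rate
    expect_equal(unname(up / dn),
                 unname((p$kfo * p$co / p$kb) * gam^2), tolerance = 1e-10)
  }
})

test_that("open-channel counting uses the majority rule", {
  p <- ryr_params()
  expect_equal(count_open_channels(matrix(c(1L, 1L, 1L, -1L), 1, 4), p), 1L)
  expect_equal(count_open_channels(matrix(-1L, 3, 4), p), 0L)
  expect_equal(count_open_channels(matrix(c(1L, 1L, -1L, -1L), 1, 4), p), 0L)
  # threshold is a parameter
  p2 <- ryr_params(open_rule_min_subunits = 2)
  expect_equal(count_open_channels(matrix(c(1L, 1L, -1L, -1L), 1, 4), p2), 1L)
})

test_that("dyadic Ca follows co + g*n_open and the state cache agrees", {
  expect_equal(local_calcium(3, ryr_params(co = 1e-9)), 75, tolerance = 1e-9)
  expect_equal(local_calcium(0, ryr_params(co = 0.1)), 0.1)
  expect_equal(local_calcium(1, ryr_params(co = 0.1)), 25.1)
  set.seed(5)
  p <- ryr_params(co = 2)
  for (rep in 1:10) {
    s <- matrix(sample(c(-1L, 1L), 24, replace = TRUE), 6, 4)
    st <- lattice_state(s, p)
    expect_equal(st$ca, local_calcium(count_open_channels(s, p), p))
  }
})

test_that("diffusion length is sqrt(4*D*tau) in nm", {
  expect_equal(diffusion_length(100, 1), sqrt(0.4) * 1000, tolerance = 1e-12)
  expect_equal(diffusion_length(250, 1), 1000)
  expect_equal(diffusion_length(100, 0), 0)
  expect_error(diffusion_length(-1, 1))
  expect_error(diffusion_length(100, -1))
})

test_that("parameter defaults match the published model constants", {
  p <- ryr_params()
  expect_equal(p$delta, 0.5)
  expect_equal(p$kfo, 0.005)
  expect_equal(p$kb, 0.3)
  expect_equal(p$g, 25)
  expect_equal(p$nc, 5L)
  expect_equal(p$open_rule_min_subunits, 3L)
})

test_that("parameter validation and JSON round trip", {
  expect_error(ryr_params(kfo = 0))
  expect_error(ryr_params(co = -1))
  expect_error(ryr_params(nc = 0))
  expect_error(ryr_params(open_rule_min_subunits = 5))
  tf <- withr::local_tempfile(fileext = ".json")
  p <- ryr_params(co = 6, sigma = 0.5)
  write_params(p, tf)
  expect_equal(read_params(tf), p)
  # unknown keys must be an error, not silently dropped
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"delta": 0.5, "kfO": 0.005}', bad)
  expect_error(read_params(bad), "unknown")
})
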