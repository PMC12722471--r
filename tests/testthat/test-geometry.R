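test_that("adjoining lattices carry two bonds per adjacent pair", {
  for (L in c(3L, 5L, 10L)) {
    g <- build_adjoining(L, L, sigma = 1)
    expect_equal(nrow(g$channels), L^2)
    pairs <- brute_adjacent_pairs(g$channels)
    expect_equal(nrow(g$bonds), 2L * pairs)
    expect_equal(nrow(g$bonds), 4L * L * (L - 1L))   # closed form
  }
  expect_equal(nrow(build_adjoining(1, 1)$bonds), 0L)
  expect_equal(nrow(build_adjoining(2, 1)$bonds), 2L)
  expect_error(build_adjoining(0, 3))
})

test_that("oblique lattices carry one 1-3 or 2-4 bond per adjacent pair", {
  for (L in c(3L, 10L)) {
    g <- build_oblique(L, L, sigma = 1)
    pairs <- brute_adjacent_pairs(g$channels)
    expect_equal(nrow(g$bonds), pairs)
    expect_equal(nrow(g$bonds), 2L * L * (L - 1L))
    types <- apply(cbind(pmin(g$bonds$i, g$bonds$j),
                         pmax(g$bonds$i, g$bonds$j)), 1,
                   paste, collapse = "-")
    expect_true(all(types %in% c("1-3", "2-4")))
  }
  expect_equal(nrow(build_oblique(1, 2)$bonds), 1L)
})

test_that("interior subunits have 2 bonds (adjoining) or 1 (oblique)", {
  count_bonds_of <- function(g, ch) {
    vapply(1:4, function(i)
      sum((g$bonds$a == ch & g$bonds$i == i) |
          (g$bonds$b == ch & g$bonds$j == i)), integer(1))
  }
  ga <- build_adjoining(3, 3)
  go <- build_oblique(3, 3)
  center <- which(ga$channels[, 1] == 2 & ga$channels[, 2] == 2)
  expect_equal(count_bonds_of(ga, center), rep(2L, 4))
  expect_equal(count_bonds_of(go, center), rep(1L, 4))
  # oblique 10x10: 40 boundary subunits are bare, the other 360 have 1 bond
  st <- geometry_stats(build_oblique(10, 10))
  expect_equal(as.integer(st$bonds_per_subunit[c("0", "1")]), c(40L, 360L))
})

test_that("bond lists are canonical and deduplicated", {
  g <- build_adjoining(4, 3)
  b <- g$bonds
  expect_true(all(b$a < b$b))
  expect_equal(order(b$a, b$b, b$i, b$j), seq_len(nrow(b)))
  expect_equal(anyDuplicated(b), 0L)
})

test_that("bond dilution retains bonds independently with probability p", {
  g <- build_adjoining(10, 10, sigma = 1)
  expect_equal(dilute_bonds(g, 1, seed = 1)$bonds, g$bonds)
  expect_equal(nrow(dilute_bonds(g, 0, seed = 1)$bonds), 0L)
  expect_error(dilute_bonds(g, 1.2))
  # Binomial(360, 0.5) oracle for the retained count across seeds
  n_seeds <- 200L
  counts <- vapply(seq_len(n_seeds), function(s)
    nrow(dilute_bonds(g, 0.5, seed = s)$bonds), integer(1))
  se_mean <- sqrt(360 * 0.25 / n_seeds)
  expect_lt(abs(mean(counts) - 180), 3 * se_mean)
  # same seed, same mask
  expect_equal(dilute_bonds(g, 0.5, seed = 7), dilute_bonds(g, 0.5, seed = 7))
})

test_that("preferential growth is uniform at alpha = 0", {
  # 500 single placements on 20x20: both coordinate margins uniform
  set.seed(42)
  xs <- integer(500); ys <- integer(500)
  for (k in 1:500) {
    g <- grow_preferential(1, 20, 20, alpha = 0)
    xs[k] <- g$channels[1, 1]; ys[k] <- g$channels[1, 2]
  }
  expect_gt(chisq.test(tabulate(xs, 20))$p.value, 0.01)
  expect_gt(chisq.test(tabulate(ys, 20))$p.value, 0.01)
})

test_that("full-grid growth reproduces the oblique lattice bonds", {
  g <- grow_preferential(12, 4, 3, alpha = 3, sigma = 1, seed = 9)
  ref <- build_oblique(4, 3, sigma = 1)
  # same bond multiset up to channel relabelling: compare as coordinate pairs
  bond_coords <- function(gg) {
    b <- gg$bonds
    e1 <- cbind(gg$channels[b$a, 1], gg$channels[b$a, 2], b$i)
    e2 <- cbind(gg$channels[b$b, 1], gg$channels[b$b, 2], b$j)
    # order the two endpoints of each bond by coordinates, not by the
    # (arbitrary) channel placement index
    k1 <- paste(e1[, 1], e1[, 2], e1[, 3])
    k2 <- paste(e2[, 1], e2[, 2], e2[, 3])
    sort(ifelse(k1 < k2, paste(k1, k2), paste(k2, k1)))
  }
  expect_equal(bond_coords(g), bond_coords(ref))
})

test_that("larger alpha grows more compact clusters", {
  mean_pairs <- function(alpha, n_cfg) {
    mean(vapply(seq_len(n_cfg), function(s)
      geometry_stats(grow_preferential(50, 20, 20, alpha, seed = 1000 + s)
                     )$adjacent_pairs, numeric(1)))
  }
  expect_gt(mean_pairs(8, 150), mean_pairs(0, 150))
  # growth is a pure function of (spec, seed)
  expect_equal(grow_preferential(50, 20, 20, 5, seed = 3),
               grow_preferential(50, 20, 20, 5, seed = 3))
  expect_error(grow_preferential(401, 20, 20, 0))
})

test_that("geometry summary statistics are consistent", {
  st <- geometry_stats(build_adjoining(10, 10))
  expect_equal(st$n_components, 1L)
  expect_equal(st$adjacent_pairs, 180L)
  st0 <- geometry_stats(dilute_bonds(build_adjoining(10, 10), 0, seed = 1))
  expect_equal(st0$n_components, 100L)
})

test_that("geometry JSON serialization round-trips exactly", {
  tf <- withr::local_tempfile(fileext = ".json")
  for (g in list(build_adjoining(3, 4, sigma = 0.5),
                 build_oblique(4, 2, sigma = 1),
                 dilute_bonds(build_adjoining(5, 5, 1), 0.4, seed = 2),
                 grow_preferential(10, 6, 6, 4, seed = 5))) {
    write_geometry(g, tf)
    expect_equal(read_geometry(tf), g)
  }
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"grid_shape":[2,2],"channels":[[1,1]],"bonds":[]}', bad)
  expect_error(read_geometry(bad), "keys")
  writeLines(paste0('{"grid_shape":[2,2],"architecture":"weird",',
                    '"channels":[[1,1]],"bonds":[]}'), bad)
  expect_error(read_geometry(bad), "architecture")
})

test_that("invalid bond lists are rejected", {
  g <- build_adjoining(2, 2)
  b <- g$bonds
  b$a[1] <- b$b[1]   # self bond
  expect_error(ryrcluster:::new_geometry(g$grid_shape, g$channels, b,
                                         "custom"), "self")
  b <- g$bonds
  b$i[1] <- 5L       # bad subunit label
  expect_error(ryrcluster:::new_geometry(g$grid_shape, g$channels, b,
                                         "custom"))
})
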