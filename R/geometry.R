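#' Cluster geometries
#'
#' An `ryr_geometry` describes where the channels of a cluster sit on a
#' lattice and which subunits of adjacent channels are physically bonded.
#' Channels are 30 nm squares occupying integer grid positions; subunits
#' 1..4 sit at the four corners in ring order 1(NW)-2(NE)-3(SE)-4(SW).
#' Inter-channel bonds are stored once, undirected and canonicalized
#' (channel index of endpoint `a` < endpoint `b`, rows sorted), each with
#' its own coupling strength `sigma`.
#'
#' Two cryo-EM contact architectures are provided:
#' * *adjoining*: side-by-side rows and columns, two subunit bonds per
#'   adjacent channel pair (right: a2-b1 and a3-b4; up: a1-b4 and a2-b3),
#'   so every interior subunit carries exactly 2 bonds;
#' * *oblique*: staggered "checkerboard" contacts, one bond per adjacent
#'   pair (right: a2-b4; up: a1-b3), bond types only 1-3 and 2-4, every
#'   interior subunit carries exactly 1 bond.
#'
#' @param nx,ny Lattice extents (positive integers).
#' @param sigma Coupling strength stored on every created bond.
#' @return An object of class `ryr_geometry`: list with `grid_shape`
#'   (c(nx, ny)), `channels` (n x 2 integer matrix of coordinates, row
#'   index = channel index), `bonds` (data.frame `a`, `i`, `b`, `j`,
#'   `sigma` with 1-based channel and subunit indices) and
#'   `architecture`.
#' @name cluster_geometry
NULL

new_geometry <- function(grid_shape, channels, bonds, architecture) {
  colnames(channels) <- c("x", "y")
  g <- structure(list(grid_shape = as.integer(grid_shape),
                      channels = channels,
                      bonds = canonicalize_bonds(bonds),
                      architecture = architecture),
                 class = "ryr_geometry")
  validate_geometry(g)
}

empty_bonds <- function() {
  data.frame(a = integer(), i = integer(), b = integer(), j = integer(),
             sigma = numeric())
}

canonicalize_bonds <- function(bonds) {
  if (nrow(bonds) == 0L) return(empty_bonds())
  swap <- bonds$a > bonds$b
  if (any(swap)) {
    tmp <- bonds[swap, ]
    bonds[swap, c("a", "i", "b", "j")] <- tmp[, c("b", "j", "a", "i")]
  }
  bonds <- unique(bonds)
  bonds <- bonds[order(bonds$a, bonds$b, bonds$i, bonds$j), , drop = FALSE]
  rownames(bonds) <- NULL
  bonds
}

validate_geometry <- function(g) {
  ch <- g$channels
  stopifnot(is.matrix(ch), ncol(ch) == 2L, nrow(ch) >= 1L,
            all(ch[, 1L] >= 1L), all(ch[, 1L] <= g$grid_shape[1L]),
            all(ch[, 2L] >= 1L), all(ch[, 2L] <= g$grid_shape[2L]))
  if (anyDuplicated(ch) > 0L) stop("duplicate channel coordinates")
  b <- g$bonds
  if (nrow(b) > 0L) {
    n <- nrow(ch)
    stopifnot(all(b$a >= 1L), all(b$a <= n), all(b$b >= 1L), all(b$b <= n),
              all(b$i %in% 1:4), all(b$j %in% 1:4),
              all(is.finite(b$sigma)))
    if (any(b$a == b$b)) stop("self bond")
    key <- paste(b$a, b$i, b$b, b$j)
    if (anyDuplicated(key) > 0L) stop("duplicate bond")
  }
  g
}

#' @export
print.ryr_geometry <- function(x, ...) {
  cat(sprintf("RyR2 cluster geometry (%s): %d channels on a %dx%d grid, %d inter-channel bonds\n",
              x$architecture, nrow(x$channels), x$grid_shape[1L],
              x$grid_shape[2L], nrow(x$bonds)))
  invisible(x)
}

# channel index of (x, y) on a fully occupied nx x ny lattice
full_index <- function(x, y, nx) (y - 1L) * nx + x

full_channels <- function(nx, ny) {
  cbind(x = rep(seq_len(nx), times = ny), y = rep(seq_len(ny), each = nx))
}

#' @rdname cluster_geometry
#' @export
build_adjoining <- function(nx, ny, sigma = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 1L, ny >= 1L, is.finite(sigma))
  bonds <- list()
  k <- 0L
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    a <- full_index(x, y, nx)
    if (x < nx) {  # right neighbour: a2-b1, a3-b4
      b <- full_index(x + 1L, y, nx)
      bonds[[k <- k + 1L]] <- data.frame(a = a, i = c(2L, 3L),
                                         b = b, j = c(1L, 4L), sigma = sigma)
    }
    if (y < ny) {  # upper neighbour: a1-b4, a2-b3
      b <- full_index(x, y + 1L, nx)
      bonds[[k <- k + 1L]] <- data.frame(a = a, i = c(1L, 2L),
                                         b = b, j = c(4L, 3L), sigma = sigma)
    }
  }
  bonds <- if (k > 0L) do.call(rbind, bonds) else empty_bonds()
  new_geometry(c(nx, ny), full_channels(nx, ny), bonds, "adjoining")
}

#' @rdname cluster_geometry
#' @export
build_oblique <- function(nx, ny, sigma = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 1L, ny >= 1L, is.finite(sigma))
  bonds <- list()
  k <- 0L
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    a <- full_index(x, y, nx)
    if (x < nx)  # right neighbour: a2-b4
      bonds[[k <- k + 1L]] <- data.frame(a = a, i = 2L,
                                         b = full_index(x + 1L, y, nx),
                                         j = 4L, sigma = sigma)
    if (y < ny)  # upper neighbour: a1-b3
      bonds[[k <- k + 1L]] <- data.frame(a = a, i = 1L,
                                         b = full_index(x, y + 1L, nx),
                                         j = 3L, sigma = sigma)
  }
  bonds <- if (k > 0L) do.call(rbind, bonds) else empty_bonds()
  new_geometry(c(nx, ny), full_channels(nx, ny), bonds, "oblique")
}

#' Bernoulli bond dilution of a cluster
#'
#' Models partial loss of cluster structural integrity: every
#' inter-channel bond is retained independently with probability `p`
#' (`p = 1` leaves the cluster intact, `p = 0` dissociates it
#' completely). Channel positions and intra-channel ring coupling are
#' untouched; disconnected channels still share the dyadic Ca pool.
#'
#' @param geometry An `ryr_geometry`.
#' @param p Retention probability in \[0, 1\].
#' @param seed Optional integer seed for reproducible masks.
#' @return A new `ryr_geometry` with `architecture = "diluted"`.
#' @export
dilute_bonds <- function(geometry, p, seed = NULL) {
  stopifnot(inherits(geometry, "ryr_geometry"),
            is.finite(p), p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  b <- geometry$bonds
  keep <- if (nrow(b) > 0L) runif(nrow(b)) < p else logical()
  new_geometry(geometry$grid_shape, geometry$channels,
               b[keep, , drop = FALSE], "diluted")
}

# von Neumann neighbours of (x, y) clipped to the grid
vn_neighbors <- function(x, y, nx, ny) {
  out <- rbind(c(x - 1L, y), c(x + 1L, y), c(x, y - 1L), c(x, y + 1L))
  out[out[, 1L] >= 1L & out[, 1L] <= nx &
      out[, 2L] >= 1L & out[, 2L] <= ny, , drop = FALSE]
}

#' Grow a heterogeneous cluster by preferential attachment
#'
#' Places `n_channels` channels one at a time on an `nx` x `ny` lattice.
#' The probability of choosing an empty site is proportional to
#' \eqn{(1 + n_e)^\alpha}, where \eqn{n_e} is the site's number of
#' occupied von Neumann neighbours. \eqn{\alpha = 0} gives uniform random
#' placement; large \eqn{\alpha} gives compact clusters. After growth,
#' every adjacent occupied pair is bonded with the oblique one-bond
#' pattern at strength `sigma`.
#'
#' @param n_channels Number of channels to place (at most `nx * ny`).
#' @param nx,ny Lattice extents.
#' @param alpha Clustering exponent \eqn{\alpha \ge 0}.
#' @param sigma Bond strength for the oblique bonds.
#' @param seed Optional integer seed.
#' @return An `ryr_geometry` with `architecture = "preferential"`.
#' @export
grow_preferential <- function(n_channels, nx, ny, alpha, sigma = 1,
                              seed = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  n_channels <- as.integer(n_channels)
  stopifnot(nx >= 1L, ny >= 1L, n_channels >= 1L,
            n_channels <= nx * ny, is.finite(alpha), alpha >= 0)
  if (!is.null(seed)) set.seed(seed)
  occupied <- matrix(FALSE, nx, ny)
  ne <- matrix(0L, nx, ny)  # occupied-neighbour counts, kept incrementally
  coords <- matrix(0L, n_channels, 2L)
  for (k in seq_len(n_channels)) {
    empty <- which(!occupied)
    w <- (1 + ne[empty])^alpha
    pick <- empty[sample.int(length(empty), 1L, prob = w)]
    x <- ((pick - 1L) %% nx) + 1L
    y <- ((pick - 1L) %/% nx) + 1L
    occupied[x, y] <- TRUE
    coords[k, ] <- c(x, y)
    nb <- vn_neighbors(x, y, nx, ny)
    ne[nb] <- ne[nb] + 1L
  }
  bond_occupied_oblique(c(nx, ny), coords, sigma, "preferential")
}

# bond every adjacent occupied pair with the oblique pattern
# (right: a2-b4, up: a1-b3)
bond_occupied_oblique <- function(grid_shape, coords, sigma, tag) {
  nx <- grid_shape[1L]; ny <- grid_shape[2L]
  idx <- matrix(0L, nx, ny)
  idx[coords] <- seq_len(nrow(coords))
  bonds <- list(); k <- 0L
  for (c0 in seq_len(nrow(coords))) {
    x <- coords[c0, 1L]; y <- coords[c0, 2L]
    if (x < nx && idx[x + 1L, y] > 0L)
      bonds[[k <- k + 1L]] <- data.frame(a = c0, i = 2L,
                                         b = idx[x + 1L, y], j = 4L,
                                         sigma = sigma)
    if (y < ny && idx[x, y + 1L] > 0L)
      bonds[[k <- k + 1L]] <- data.frame(a = c0, i = 1L,
                                         b = idx[x, y + 1L], j = 3L,
                                         sigma = sigma)
  }
  bonds <- if (k > 0L) do.call(rbind, bonds) else empty_bonds()
  new_geometry(grid_shape, coords, bonds, tag)
}

#' Summary statistics of a cluster geometry
#'
#' @param geometry An `ryr_geometry`.
#' @return A list: `n_channels`, `n_bonds`, `adjacent_pairs` (count of
#'   von-Neumann-adjacent occupied channel pairs, bonded or not),
#'   `bonds_per_subunit` (table over all 4n subunits), and
#'   `n_components` (connected components of the channel graph induced by
#'   the bonds; isolated channels count as their own component).
#' @export
geometry_stats <- function(geometry) {
  stopifnot(inherits(geometry, "ryr_geometry"))
  ch <- geometry$channels
  n <- nrow(ch)
  b <- geometry$bonds
  # adjacent occupied pairs by brute-force coordinate comparison
  dx <- abs(outer(ch[, 1L], ch[, 1L], "-"))
  dy <- abs(outer(ch[, 2L], ch[, 2L], "-"))
  adj <- (dx + dy) == 1L
  adjacent_pairs <- sum(adj[upper.tri(adj)])
  per_sub <- integer(4L * n)
  if (nrow(b) > 0L) {
    ia <- (b$a - 1L) * 4L + b$i
    ib <- (b$b - 1L) * 4L + b$j
    tab <- table(c(ia, ib))
    per_sub[as.integer(names(tab))] <- as.integer(tab)
  }
  gr <- igraph::graph_from_data_frame(
    data.frame(from = c(b$a, integer()), to = c(b$b, integer())),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  list(n_channels = n,
       n_bonds = nrow(b),
       adjacent_pairs = adjacent_pairs,
       bonds_per_subunit = table(per_sub),
       n_components = igraph::components(gr)$no)
}

#' Read / write cluster geometries as JSON
#'
#' Format: `{"grid_shape":[nx,ny], "architecture":"oblique",
#' "channels":[[x,y],...], "bonds":[[a,i,b,j,sigma],...]}` with 0-based
#' channel indices `a`, `b` into the `channels` list and 1-based subunit
#' labels `i`, `j`. Coordinates are 1-based lattice positions. Round
#' trips are exact.
#'
#' @param geometry An `ryr_geometry`.
#' @param path File path.
#' @return `write_geometry` returns `path` invisibly; `read_geometry`
#'   returns a validated `ryr_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "ryr_geometry"))
  b <- geometry$bonds
  bonds <- unname(lapply(seq_len(nrow(b)), function(r)
    c(b$a[r] - 1L, b$i[r], b$b[r] - 1L, b$j[r], b$sigma[r])))
  obj <- list(grid_shape = geometry$grid_shape,
              architecture = geometry$architecture,
              channels = unname(lapply(seq_len(nrow(geometry$channels)),
                                       function(r) geometry$channels[r, ])),
              bonds = bonds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  req <- c("grid_shape", "architecture", "channels", "bonds")
  if (!setequal(names(x), req))
    stop("geometry JSON must have exactly the keys ",
         paste(req, collapse = ", "))
  grid_shape <- as.integer(unlist(x$grid_shape))
  stopifnot(length(grid_shape) == 2L)
  channels <- do.call(rbind, lapply(x$channels, function(v) {
    v <- as.integer(unlist(v))
    if (length(v) != 2L) stop("each channel entry must be [x, y]")
    v
  }))
  bonds <- if (length(x$bonds) > 0L) {
    do.call(rbind, lapply(x$bonds, function(v) {
      v <- as.numeric(unlist(v))
      if (length(v) != 5L) stop("each bond entry must be [a,i,b,j,sigma]")
      data.frame(a = as.integer(v[1L]) + 1L, i = as.integer(v[2L]),
                 b = as.integer(v[3L]) + 1L, j = as.integer(v[4L]),
                 sigma = v[5L])
    }))
  } else empty_bonds()
  arch <- as.character(x$architecture)
  if (!arch %in% c("adjoining", "oblique", "diluted", "preferential",
                   "custom"))
    stop("unknown architecture tag: ", arch)
  new_geometry(grid_shape, channels, bonds, arch)
}
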