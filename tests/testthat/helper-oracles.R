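# Independent oracles and fixture builders used across the suite.

# Scalar queue-based BFS flood fill, deliberately written as a plain
# breadth-first search so it shares no code with the package's vectorised
# frontier engine. `band` is a logical array (2-D or 3-D), `seed` a 1-based
# index vector. In-plane connectivity 4 or 8; `link_z` adds +-z adjacency.
bfs_flood_oracle <- function(band, seed, connectivity = 4, link_z = FALSE) {
  d <- dim(band)
  if (length(d) == 2L) {
    band <- array(band, c(d, 1L))
    d <- dim(band)
    seed <- c(seed, 1L)
  }
  offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  if (connectivity == 8) {
    offs <- c(offs, list(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0)))
  }
  if (link_z) offs <- c(offs, list(c(0, 0, 1), c(0, 0, -1)))
  visited <- array(FALSE, d)
  if (!band[seed[1], seed[2], seed[3]]) return(visited)
  queue <- list(seed)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (off in offs) {
      nb <- cur + off
      if (any(nb < 1L) || any(nb > d)) next
      if (band[nb[1], nb[2], nb[3]] && !visited[nb[1], nb[2], nb[3]]) {
        visited[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1L]] <- nb
      }
    }
  }
  visited
}

# Paired samples whose differences have exactly the requested mean and
# sample SD (n - 1 denominator): b is zero, a carries the differences.
pairs_with_moments <- function(bias, sd_diff, n = 30) {
  z <- seq_len(n)
  z <- (z - mean(z)) / stats::sd(z)
  list(a = bias + sd_diff * z, b = rep(0, n))
}

# A vector with exactly the requested mean and sample SD.
vector_with_moments <- function(mean, sd, n = 30) {
  z <- seq_len(n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

# Coarse-grid phantom spec: the default anatomy voxelised at 8 mm, small
# enough for repeated use in tests.
coarse_spec <- function(preset = "breathhold", ...) {
  phantom_spec(preset, grid_shape = c(48L, 48L, 42L), spacing_mm = c(8, 8, 8), ...)
}

# Cached coarse phantoms (geometry is deterministic; reuse across tests).
local_coarse_phantom <- local({
  cache <- new.env()
  function(preset = "breathhold", ...) {
    key <- paste(preset, deparse(list(...)), collapse = "|")
    if (is.null(cache[[key]])) cache[[key]] <- generate_phantom(coarse_spec(preset, ...))
    cache[[key]]
  }
})
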