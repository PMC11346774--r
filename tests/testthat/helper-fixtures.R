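# shared fixtures: exact local lattice patches, bonded periodic lattices,
# random configurations, and small MC protocols used across test files

mb <- rose_parameters("mb")
real <- rose_parameters("real")

# a configuration object from raw vectors (box side L)
raw_config <- function(x, y, phi, L) {
  structure(list(N = length(x), L = L, x = x, y = y, phi = phi,
                 ux = numeric(length(x)), uy = numeric(length(x))),
            class = "rose_configuration")
}

# one particle with k neighbours at exact angles (degrees), distance d,
# isolated in a large box; particle 1 is the centre
star_patch <- function(angles_deg, d = 1, L = 50, phi = NULL) {
  a <- angles_deg * pi / 180
  x <- c(L / 2, L / 2 + d * cos(a))
  y <- c(L / 2, L / 2 + d * sin(a))
  n <- length(x)
  if (is.null(phi)) phi <- numeric(n)
  raw_config(x, y, phi, L)
}

# periodic honeycomb at hydrogen-bond distance with every molecule oriented
# so that all three arms point at its neighbours (rose minima at
# theta = -pi/6 + 2k pi/3 in the body frame)
bonded_honeycomb <- function(N = 72, p = mb) {
  rho <- 4 / (3 * sqrt(3) * p$r_hb^2)  # ideal honeycomb number density
  cfg <- init_configuration(state_point(rho, 0.1), N, "honeycomb", seed = 1)
  dx <- rosewater:::min_image(outer(cfg$x, cfg$x, "-"), cfg$L)
  dy <- rosewater:::min_image(outer(cfg$y, cfg$y, "-"), cfg$L)
  r <- sqrt(dx^2 + dy^2)
  for (i in seq_len(cfg$N)) {
    j <- which(r[, i] > 0 & r[, i] < 1.2)[1]  # first neighbour of i
    psi <- atan2(dy[j, i], dx[j, i])
    cfg$phi[i] <- psi + pi / 6
  }
  cfg
}

# quick MC protocols (kept tiny; these back sanity tests, not statistics)
tiny_settings <- function(seed = 1, ...) {
  mc_settings(n_equil_cycles = 2000, n_series = 4, cycles_per_series = 2000,
              rng_seed = seed, ...)
}

# random particle triple (x, y, phi) in a box
rand_state <- function(L) c(runif(1, 0, L), runif(1, 0, L), runif(1, -pi, pi))
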