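#' Radial distribution function of sampled configurations
#'
#' Standard 2D normalisation: directed pair counts in each annulus divided by
#' `N * rho * pi * ((r + dr)^2 - r^2)`, averaged over frames and reference
#' particles, accumulated out to half the box length.  With this convention
#' `rho * integral( g(r) 2 pi r dr )` over the full range counts the `N - 1`
#' partners of a particle.
#'
#' @param frames A single `rose_configuration` or a list of them (all sharing
#'   `N` and `L`), e.g. from [read_frames()] or a run with
#'   `store_frames = TRUE`.
#' @param sp A [state_point()] (density must match the frames).
#' @param bin_width Bin width, `r_hb` units.
#' @return An object of class `"rose_rdf"`: list with bin midpoints `r`,
#'   values `g`, `bin_width`, `rho` and the range `r_c = L/2`.
#' @export
compute_rdf <- function(frames, sp, bin_width = 0.02) {
  if (inherits(frames, "rose_configuration")) frames <- list(frames)
  stopifnot(length(frames) >= 1, bin_width > 0,
            inherits(sp, "state_point"))
  L <- frames[[1]]$L
  N <- frames[[1]]$N
  nb <- floor(0.5 * L / bin_width)
  edges <- bin_width * (0:nb)
  counts <- numeric(nb)
  for (f in frames) {
    d <- config_pair_distances(f)
    h <- graphics::hist(d[d < edges[nb + 1]], breaks = edges, plot = FALSE)
    counts <- counts + h$counts
  }
  annulus <- pi * (edges[-1]^2 - edges[-(nb + 1)]^2)
  g <- 2 * counts / (length(frames) * N * sp$rho * annulus)
  structure(list(r = (edges[-1] + edges[-(nb + 1)]) / 2, g = g,
                 bin_width = bin_width, rho = sp$rho, r_c = L / 2),
            class = "rose_rdf")
}

#' Translational order parameter
#'
#' \eqn{t = \rho^{1/2} \int_0^{r_c} |g(r) - 1| \, dr} with
#' \eqn{r_c = L/2}, by trapezoidal quadrature over the RDF bins.  Zero for an
#' ideal gas; grows with pair correlation.
#'
#' @param rdf A `"rose_rdf"` object.
#' @return Dimensionless `t >= 0`.
#' @export
translational_order <- function(rdf) {
  stopifnot(inherits(rdf, "rose_rdf"))
  sqrt(rdf$rho) * trapz(rdf$r, abs(rdf$g - 1))
}

#' Pair entropy
#'
#' Two-body contribution to the excess entropy in 2D,
#' \eqn{s_2 = -\pi\rho \int_0^{L/2} [g \ln g - g + 1] \, r \, dr}
#' (in units of \eqn{k_B} per particle), by trapezoidal quadrature.  Bins
#' with `g = 0` contribute the integrand's limit value 1
#' (`g ln g -> 0`).  Zero iff `g` is identically 1 on the domain.
#'
#' @param rdf A `"rose_rdf"` object.
#' @return `s2` (dimensionless).
#' @export
pair_entropy <- function(rdf) {
  stopifnot(inherits(rdf, "rose_rdf"))
  g <- rdf$g
  gl <- ifelse(g > 0, g * log(g), 0)
  -pi * rdf$rho * trapz(rdf$r, (gl - g + 1) * rdf$r)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Bond-orientational order parameter
#'
#' Per particle, \eqn{q_l^i = n_i^{-1} \sum_k \exp(i l \theta_{ik})} over the
#' first-shell neighbours `k` of `i` (minimum-image distance below
#' `shell_cutoff`), with \eqn{\theta_{ik}} the lab-frame angle of the
#' connecting vector against the horizontal axis.  The system value is the
#' average of the per-particle magnitudes; particles with no neighbours
#' contribute zero.  `l = 3` probes honeycomb-like, `l = 6` triangular-like
#' order.
#'
#' @param frame A `rose_configuration`.
#' @param l Symmetry order, 3 or 6 (any positive integer accepted).
#' @param shell_cutoff First-shell distance, `r_hb` units (default 1.2, the
#'   first RDF minimum after the hydrogen-bond peak).
#' @return List with `q_l` (scalar in `[0, 1]`), per-particle magnitudes
#'   `q_l_i`, and neighbour counts `n_neighbors`.
#' @export
orientational_order <- function(frame, l = 6, shell_cutoff = 1.2) {
  stopifnot(inherits(frame, "rose_configuration"), l >= 1)
  N <- frame$N
  dx <- min_image(outer(frame$x, frame$x, "-"), frame$L)
  dy <- min_image(outer(frame$y, frame$y, "-"), frame$L)
  r <- sqrt(dx^2 + dy^2)
  nb <- r < shell_cutoff & r > 0
  qli <- numeric(N)
  nn <- integer(N)
  for (i in seq_len(N)) {
    k <- which(nb[, i])  # column i: displacements x[k] - x[i] seen from i
    nn[i] <- length(k)
    if (length(k) > 0) {
      ph <- l * atan2(dy[k, i], dx[k, i])
      qli[i] <- Mod(sum(exp(1i * ph))) / length(k)
    }
  }
  list(q_l = mean(qli), q_l_i = qli, n_neighbors = nn, l = l,
       shell_cutoff = shell_cutoff)
}

#' Hydrogen bonds per molecule
#'
#' Energetic bond criterion: molecule `i` donates a half bond to `j` when its
#' half-bond energy ([hb_half_energy()]) is below `threshold`; a full
#' hydrogen bond exists when both halves qualify.  Returns twice the full
#' bond count per particle (each bond is shared by two molecules), plus the
#' half-bond tally.
#'
#' @param frame A `rose_configuration`.
#' @param p A [rose_parameters()] object.
#' @param threshold Half-bond energy threshold in `eps_hb` units
#'   (default `-0.125`).
#' @return List with `hb_per_molecule`, `n_bonds`, `n_half_bonds`.
#' @export
hb_count <- function(frame, p, threshold = -0.125) {
  stopifnot(inherits(frame, "rose_configuration"), threshold <= 0)
  thr <- threshold * p$eps_hb
  N <- frame$N
  dx <- min_image(outer(frame$x, frame$x, "-"), frame$L)
  dy <- min_image(outer(frame$y, frame$y, "-"), frame$L)
  r <- sqrt(dx^2 + dy^2)
  bonds <- 0L
  halves <- 0L
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (j <= i) next
      if (r[i, j] <= p$r_l || r[i, j] >= p$r_u) next
      # dx[j, i] = x[j] - x[i]: displacement from i to its partner j
      th_ij <- body_frame_angle(c(dx[j, i], dy[j, i]), frame$phi[i])
      th_ji <- body_frame_angle(c(-dx[j, i], -dy[j, i]), frame$phi[j])
      hi <- hb_half_energy(r[i, j], th_ij, p) < thr
      hj <- hb_half_energy(r[i, j], th_ji, p) < thr
      if (hi && hj) bonds <- bonds + 1L
      else if (hi || hj) halves <- halves + 1L
    }
  }
  list(hb_per_molecule = 2 * bonds / N, n_bonds = bonds,
       n_half_bonds = halves)
}
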