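#' Lennard-Jones pair energy
#'
#' Standard 12-6 form \eqn{4\epsilon_{LJ}[(\sigma/r)^{12} - (\sigma/r)^6]}.
#'
#' @param r Centre-centre distance(s), `r_hb` units. Must be positive.
#' @param p A [rose_parameters()] object.
#' @return Energy in `eps_hb` units (vectorised over `r`).
#' @examples
#' p <- rose_parameters("mb")
#' lj_pair_energy(2^(1/6) * p$sigma_lj, p) # -eps_lj at the minimum
#' @export
lj_pair_energy <- function(r, p) {
  if (any(r <= 0)) stop("degenerate pair: r must be > 0")
  sr6 <- (p$sigma_lj / r)^6
  4 * p$eps_lj * (sr6 * sr6 - sr6)
}

# d u_LJ / d r (needed for the radial virial)
lj_pair_dudr <- function(r, p) {
  sr6 <- (p$sigma_lj / r)^6
  -24 * p$eps_lj * (2 * sr6 * sr6 - sr6) / r
}

#' Double-sided cubic switching function of the hydrogen-bond window
#'
#' Radial factor of the HB term: 0 outside `[r_l, r_u)`, 1 at `r_hb`, with the
#' two cubic arcs meeting smoothly (zero slope at `r_l`, `r_hb` and `r_u`) and
#' crossing 0.5 at the half-width points, which is what makes `r_fwhm` a full
#' width at half maximum.
#'
#' @inheritParams lj_pair_energy
#' @return Dimensionless value(s) in `[0, 1]`.
#' @export
switching_s <- function(r, p) {
  s <- numeric(length(r))
  lo <- r >= p$r_l & r < p$r_hb
  hi <- r >= p$r_hb & r < p$r_u
  d3l <- (p$r_l - p$r_hb)^3
  d3u <- (p$r_u - p$r_hb)^3
  s[lo] <- (p$r_l + 2 * r[lo] - 3 * p$r_hb) * (p$r_l - r[lo])^2 / d3l
  s[hi] <- (p$r_u + 2 * r[hi] - 3 * p$r_hb) * (p$r_u - r[hi])^2 / d3u
  s
}

# d s / d r, analytic (zero outside the window)
switching_dsdr <- function(r, p) {
  ds <- numeric(length(r))
  lo <- r >= p$r_l & r < p$r_hb
  hi <- r >= p$r_hb & r < p$r_u
  # d/dr [(b + 2r - 3 r_hb)(b - r)^2] / (b - r_hb)^3 = 6 (b-r)(r_hb - r)/(b - r_hb)^3
  ds[lo] <- 6 * (p$r_l - r[lo]) * (p$r_hb - r[lo]) / (p$r_l - p$r_hb)^3
  ds[hi] <- 6 * (p$r_u - r[hi]) * (p$r_hb - r[hi]) / (p$r_u - p$r_hb)^3
  ds
}

#' Angular rose function of the hydrogen-bonding potential
#'
#' Three-petal rose profile \eqn{U(\theta) = a_2 \sin^2(3\theta) +
#' a_1 \sin(3\theta)}, periodic with period \eqn{2\pi/3}.  With the preset
#' coefficients (`a1 = 0.7`, `a2 = -0.3`) its minimum over angle is exactly
#' \eqn{-1} (at \eqn{\sin 3\theta = -1}) and its maximum \eqn{0.4}, so a fully
#' formed bond contributes \eqn{-\epsilon_{HB}}.
#'
#' @param theta Angle(s) in radians (any real value; the function is periodic).
#' @param p A [rose_parameters()] object.
#' @return Dimensionless value(s).
#' @export
angular_U <- function(theta, p) {
  u <- sin(3 * theta)
  p$a2 * u * u + p$a1 * u
}

#' Body-frame polar angle of a displacement vector
#'
#' Rotates the lab frame by `-phi` (the molecule's orientation) and returns
#' the polar angle of the displacement in that body frame, reduced to
#' `[-pi, pi)`.  Equivariant: rotating both the displacement and `phi` by a
#' common angle leaves the result unchanged.
#'
#' @param displacement Numeric length-2 vector (dx, dy), non-zero.
#' @param phi Orientation of the molecule, radians.
#' @return Angle in radians in `[-pi, pi)`.
#' @export
body_frame_angle <- function(displacement, phi) {
  dx <- displacement[1]; dy <- displacement[2]
  if (dx == 0 && dy == 0) stop("degenerate pair: zero displacement vector")
  wrap_angle(atan2(dy, dx) - phi)
}

# reduce angle(s) to [-pi, pi)
wrap_angle <- function(a) {
  a - 2 * pi * floor((a + pi) / (2 * pi))
}

#' One molecule's half of the hydrogen-bonding pair energy
#'
#' \eqn{(\epsilon_{HB}/2)\, s(r)\, U(\theta)}: the independent contribution of
#' one molecule of a pair, where `theta` is the direction to the partner seen
#' in this molecule's body frame.  The factor \eqn{1/2} normalises the optimal
#' full bond (both halves at the angular minimum, `r = r_hb`) to
#' \eqn{-\epsilon_{HB}}.
#'
#' @param r Centre-centre distance (must be positive).
#' @param theta Direction to the partner in this molecule's body frame, rad.
#' @param p A [rose_parameters()] object.
#' @return Energy in `eps_hb` units.
#' @export
hb_half_energy <- function(r, theta, p) {
  if (any(r <= 0)) stop("degenerate pair: r must be > 0")
  0.5 * p$eps_hb * switching_s(r, p) * angular_U(theta, p)
}

# Cartesian form of the half-bond energy: x, y are partner coordinates in the
# molecule's body frame.  Algebraically identical to hb_half_energy via
# sin(3 theta) = (3 x^2 y - y^3) / r^3; kept as the cross-check route.
hb_half_energy_cartesian <- function(x, y, p) {
  r2 <- x * x + y * y
  r <- sqrt(r2)
  if (any(r == 0)) stop("degenerate pair: r must be > 0")
  w <- 3 * x * x * y - y^3
  r3 <- r2 * r
  0.5 * p$eps_hb * switching_s(r, p) *
    (p$a2 * (w / r3)^2 + p$a1 * w / r3)
}

# minimum-image displacement xj - xi in a square box of side L
min_image <- function(d, L) d - L * round(d / L)

#' Full rose pair energy of two molecules
#'
#' \eqn{U_{LJ}(r) + U_{HB}(i \to j) + U_{HB}(j \to i)} with `r` the
#' minimum-image centre distance.  Each molecule is given as `c(x, y, phi)`.
#' Symmetric under exchange of the two molecules.
#'
#' @param xi,xj Numeric length-3 vectors `(x, y, phi)`.
#' @param p A [rose_parameters()] object.
#' @param box Box side length `L` (periodic square box), or `Inf` for an open
#'   system.
#' @return Energy in `eps_hb` units.
#' @examples
#' p <- rose_parameters("mb")
#' # optimal full hydrogen bond at r = r_hb: -1 plus the LJ value at 1
#' xi <- c(0, 0, pi / 6)
#' xj <- c(1, 0, pi + pi / 6)
#' pair_energy(xi, xj, p, box = 20)
#' @export
pair_energy <- function(xi, xj, p, box = Inf) {
  dx <- xj[1] - xi[1]; dy <- xj[2] - xi[2]
  if (is.finite(box)) { dx <- min_image(dx, box); dy <- min_image(dy, box) }
  r <- sqrt(dx * dx + dy * dy)
  if (r == 0) stop("degenerate pair: coincident particles")
  e <- lj_pair_energy(r, p)
  if (r > p$r_l && r < p$r_u) {
    th_ij <- body_frame_angle(c(dx, dy), xi[3])
    th_ji <- body_frame_angle(c(-dx, -dy), xj[3])
    e <- e + hb_half_energy(r, th_ij, p) + hb_half_energy(r, th_ji, p)
  }
  e
}

#' Radial virial of a rose pair
#'
#' Returns \eqn{r\, du/dr} at fixed orientations and fixed bond direction:
#' \eqn{r[U_{LJ}'(r) + (\epsilon_{HB}/2)(U(\theta_{ij}) + U(\theta_{ji}))
#' s'(r)]}.  The angular factors depend only on direction, so they contribute
#' no radial derivative; this is the pair term entering the 2D virial
#' pressure.
#'
#' @inheritParams pair_energy
#' @return \eqn{r \, du/dr} in `eps_hb` units.
#' @export
pair_radial_virial <- function(xi, xj, p, box = Inf) {
  dx <- xj[1] - xi[1]; dy <- xj[2] - xi[2]
  if (is.finite(box)) { dx <- min_image(dx, box); dy <- min_image(dy, box) }
  r <- sqrt(dx * dx + dy * dy)
  if (r == 0) stop("degenerate pair: coincident particles")
  dudr <- lj_pair_dudr(r, p)
  if (r > p$r_l && r < p$r_u) {
    th_ij <- body_frame_angle(c(dx, dy), xi[3])
    th_ji <- body_frame_angle(c(-dx, -dy), xj[3])
    dudr <- dudr + 0.5 * p$eps_hb *
      (angular_U(th_ij, p) + angular_U(th_ji, p)) * switching_dsdr(r, p)
  }
  r * dudr
}

#' Total potential energy of a configuration
#'
#' Sum of [pair_energy()] over all distinct pairs within the interaction
#' cutoff, using the minimum-image convention.  Evaluated by the compiled
#' neighbour-list engine; [brute_force_energy()] is the plain double-loop
#' reference.
#'
#' @param config A `rose_configuration` (see [init_configuration()]).
#' @param p A [rose_parameters()] object.
#' @return Total energy in `eps_hb` units.
#' @export
total_energy <- function(config, p) {
  stopifnot(inherits(config, "rose_configuration"))
  rc <- resolve_cutoff(p, config$L)
  total_energy_cpp(config$x, config$y, config$phi, config$L,
                   unclass_params(p), rc)
}

# plain named numeric vector for the C++ side
unclass_params <- function(p) {
  c(eps_lj = p$eps_lj, sigma_lj = p$sigma_lj, eps_hb = p$eps_hb,
    r_hb = p$r_hb, r_l = p$r_l, r_u = p$r_u, a1 = p$a1, a2 = p$a2)
}
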