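test_that("parameter presets reproduce the two published parameter sets", {
  expect_equal(mb$eps_lj, 0.1)
  expect_equal(mb$sigma_lj, 0.7)
  expect_equal(mb$eps_hb, 1)
  expect_equal(mb$r_hb, 1)
  expect_equal(mb$r_fwhm, 0.35)
  expect_equal(mb$a1, 0.7)
  expect_equal(mb$a2, -0.3)
  expect_equal(mb$r_l, 0.65)
  expect_equal(mb$r_u, 1.35)
  # real preset differs only in the LJ block; sigma puts the LJ minimum at r_hb
  expect_equal(real$eps_lj, 0.2)
  expect_equal(real$sigma_lj, 0.890899)
  expect_equal(real$sigma_lj, 2^(-1 / 6), tolerance = 1e-6)
  for (f in c("eps_hb", "r_hb", "r_fwhm", "a1", "a2")) {
    expect_identical(real[[f]], mb[[f]])
  }
  expect_error(rose_parameters(eps_lj = 0.1), "missing parameter")
  expect_error(rose_parameters("mb", r_cut = 1.0), "r_cut")
})

test_that("Lennard-Jones term has its textbook minimum and zero crossing", {
  for (p in list(mb, real)) {
    expect_equal(lj_pair_energy(2^(1 / 6) * p$sigma_lj, p), -p$eps_lj)
    expect_equal(lj_pair_energy(p$sigma_lj, p), 0)
  }
  # hand-evaluated value at the hydrogen-bond distance, MB parameters
  expect_equal(lj_pair_energy(1, mb), 0.4 * (0.7^12 - 0.7^6))
  expect_equal(lj_pair_energy(1, mb), -0.0415230851196, tolerance = 1e-12)
  expect_error(lj_pair_energy(0, mb), "degenerate")
})

test_that("switching function hits its anchor values and stays in [0,1]", {
  expect_equal(switching_s(mb$r_hb, mb), 1)
  expect_equal(switching_s(mb$r_l, mb), 0)
  expect_equal(switching_s(mb$r_u, mb), 0)
  # half-maximum at the half-width points on both sides (the FWHM property)
  expect_equal(switching_s((mb$r_l + mb$r_hb) / 2, mb), 0.5)
  expect_equal(switching_s((mb$r_hb + mb$r_u) / 2, mb), 0.5)
  r <- seq(0, 2, 1e-3)
  s <- switching_s(r, mb)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(s[r < mb$r_l] == 0))
  expect_true(all(s[r >= mb$r_u] == 0))
})

test_that("switching function is continuous with zero slope at its knots", {
  h <- 1e-7
  for (r0 in c(mb$r_l, mb$r_hb, mb$r_u)) {
    # continuity
    expect_equal(switching_s(r0 - h, mb), switching_s(r0 + h, mb),
                 tolerance = 1e-5)
    # one-sided slopes vanish
    left <- (switching_s(r0, mb) - switching_s(r0 - h, mb)) / h
    right <- (switching_s(r0 + h, mb) - switching_s(r0, mb)) / h
    expect_lt(abs(left), 1e-5)
    expect_lt(abs(right), 1e-5)
  }
  # analytic derivative agrees with central differences inside the window
  r <- seq(0.66, 1.34, 0.02)
  num <- (switching_s(r + 1e-6, mb) - switching_s(r - 1e-6, mb)) / 2e-6
  expect_equal(rosewater:::switching_dsdr(r, mb), num, tolerance = 1e-6)
})

test_that("rose angular profile: anchors, periodicity, and exact range", {
  expect_equal(angular_U(0, mb), 0)
  expect_equal(angular_U(-pi / 6, mb), -1)  # sin(3 theta) = -1 arm minimum
  th <- seq(-pi, pi, length.out = 101)
  expect_equal(angular_U(th + 2 * pi / 3, mb), angular_U(th, mb))
  # analytic extrema of a2 u^2 + a1 u over u in [-1, 1]: a2 < 0, a1 > 0
  # puts the minimum at u = -1 (a2 - a1 = -1) and the maximum at u = 1 (0.4);
  # cross-check numerically on a fine grid
  u <- seq(-1, 1, 1e-4)
  g <- mb$a2 * u^2 + mb$a1 * u
  expect_equal(min(angular_U(seq(0, 2 * pi / 3, 1e-4), mb)), min(g),
               tolerance = 1e-6)
  expect_equal(min(g), -1)
  expect_equal(max(angular_U(seq(0, 2 * pi / 3, 1e-4), mb)), max(g),
               tolerance = 1e-6)
  expect_equal(max(g), 0.4)
})

test_that("body-frame angle co-rotates with the molecule", {
  expect_equal(body_frame_angle(c(1, 0), 0), 0)
  expect_equal(body_frame_angle(c(0, 1), pi / 2), 0)
  expect_equal(body_frame_angle(c(1, 0), pi / 3), -pi / 3)
  expect_error(body_frame_angle(c(0, 0), 0), "degenerate")
  set.seed(42)
  for (k in 1:50) {
    v <- stats::rnorm(2)
    phi <- runif(1, -10, 10)
    alpha <- runif(1, -10, 10)
    rot <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2)
    expect_equal(body_frame_angle(as.vector(rot %*% v), phi + alpha),
                 body_frame_angle(v, phi))
  }
})

test_that("half-bond energy: normalisation, window, Cartesian identity", {
  # one optimal half bond is worth -eps_hb / 2
  expect_equal(hb_half_energy(mb$r_hb, -pi / 6, mb), -0.5)
  expect_equal(hb_half_energy(0.5, 1.0, mb), 0)   # below the window
  expect_equal(hb_half_energy(1.5, 1.0, mb), 0)   # above the window
  set.seed(7)
  for (k in 1:100) {
    xy <- stats::rnorm(2)
    r <- sqrt(sum(xy^2))
    th <- atan2(xy[2], xy[1])
    expect_equal(rosewater:::hb_half_energy_cartesian(xy[1], xy[2], mb),
                 hb_half_energy(r, th, mb), tolerance = 1e-12)
  }
})

test_that("pair energy: optimal bond, half bond, exchange symmetry", {
  # both molecules see each other at a rose minimum at r = r_hb
  xi <- c(0, 0, pi / 6)
  xj <- c(1, 0, pi + pi / 6)
  e_opt <- pair_energy(xi, xj, mb, box = 20)
  expect_equal(e_opt, -mb$eps_hb + lj_pair_energy(1, mb), tolerance = 1e-12)
  # rotate molecule j to a zero of the rose function: half bond remains
  xj_half <- c(1, 0, pi)  # j sees i at body angle 0, where U = 0
  e_half <- pair_energy(xi, xj_half, mb, box = 20)
  expect_equal(e_half - lj_pair_energy(1, mb),
               (e_opt - lj_pair_energy(1, mb)) / 2, tolerance = 1e-12)
  set.seed(11)
  for (k in 1:100) {
    a <- rand_state(10); b <- rand_state(10)
    expect_equal(pair_energy(a, b, mb, 10), pair_energy(b, a, mb, 10))
  }
  expect_error(pair_energy(c(1, 1, 0), c(1, 1, 2), mb, 10), "degenerate")
})

test_that("pair energy is invariant under global translation and rotation", {
  set.seed(13)
  for (k in 1:25) {
    a <- c(stats::rnorm(2), runif(1, -pi, pi))
    b <- c(stats::rnorm(2), runif(1, -pi, pi))
    e <- pair_energy(a, b, mb, box = Inf)
    tr <- stats::rnorm(2)
    expect_equal(pair_energy(c(a[1:2] + tr, a[3]), c(b[1:2] + tr, b[3]),
                             mb, box = Inf), e)
    al <- runif(1, -pi, pi)
    rot <- matrix(c(cos(al), sin(al), -sin(al), cos(al)), 2)
    ar <- c(as.vector(rot %*% a[1:2]), a[3] + al)
    br <- c(as.vector(rot %*% b[1:2]), b[3] + al)
    expect_equal(pair_energy(ar, br, mb, box = Inf), e)
  }
})

test_that("radial virial matches a central-difference derivative", {
  p0 <- rose_parameters("mb", eps_hb = 0)
  expect_equal(pair_radial_virial(c(0, 0, 0), c(2^(1 / 6) * 0.7, 0, 0),
                                  p0, 20), 0, tolerance = 1e-10)
  set.seed(17)
  h <- 1e-6
  for (k in 1:40) {
    r <- runif(1, 0.5, 1.6)
    dir <- runif(1, -pi, pi)
    pa <- runif(1, -pi, pi); pb <- runif(1, -pi, pi)
    at_r <- function(rr) {
      pair_energy(c(0, 0, pa), c(rr * cos(dir), rr * sin(dir), pb), mb, 20)
    }
    num <- r * (at_r(r + h) - at_r(r - h)) / (2 * h)
    expect_equal(pair_radial_virial(c(0, 0, pa),
                                    c(r * cos(dir), r * sin(dir), pb),
                                    mb, 20),
                 num, tolerance = 1e-6)
  }
  # outside the switching window only the LJ derivative remains
  r <- 1.5
  expect_equal(pair_radial_virial(c(0, 0, 0.3), c(r, 0, 1.1), mb, 20),
               r * rosewater:::lj_pair_dudr(r, mb))
})

test_that("engine total energy equals the brute-force double loop", {
  sp <- state_point(0.5, 0.2)
  expect_equal(total_energy(init_configuration(sp, 1, seed = 1), mb), 0)
  set.seed(19)
  for (k in 1:30) {
    cfg <- init_configuration(sp, 20, "random", seed = 100 + k)
    expect_equal(total_energy(cfg, mb), brute_force_energy(cfg, mb),
                 tolerance = 1e-10)
  }
  # neighbour-list path (N >= 50) against the same R oracle, both presets
  for (p in list(mb, real)) {
    cfg <- init_configuration(state_point(0.9, 0.15), 100, "random", seed = 3)
    expect_equal(total_energy(cfg, p), brute_force_energy(cfg, p),
                 tolerance = 1e-10)
  }
})

test_that("total energy is invariant under global translation mod the box", {
  cfg <- init_configuration(state_point(0.8, 0.2), 36, "random", seed = 5)
  e <- total_energy(cfg, mb)
  shifted <- cfg
  shifted$x <- (cfg$x + 1.2345) %% cfg$L
  shifted$y <- (cfg$y + 4.321) %% cfg$L
  expect_equal(total_energy(shifted, mb), e, tolerance = 1e-10)
})
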