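ideal <- rose_parameters("mb", eps_lj = 0, eps_hb = 0)

test_that("initial configurations honour density, box and RNG contracts", {
  sp <- state_point(0.9, 0.15)
  cfg <- init_configuration(sp, 64, "random", seed = 1)
  expect_equal(cfg$N / cfg$L^2, 0.9)
  expect_true(all(cfg$x >= 0 & cfg$x < cfg$L))
  expect_true(all(cfg$y >= 0 & cfg$y < cfg$L))
  cfg2 <- init_configuration(sp, 64, "random", seed = 1)
  expect_identical(cfg, cfg2)
  cfg3 <- init_configuration(sp, 64, "random", seed = 2)
  expect_false(identical(cfg$x, cfg3$x))
})

test_that("lattice starts have the right coordination shells", {
  # honeycomb at the density whose bond length is r_hb: 3 neighbours < 1.2
  rho_hc <- 4 / (3 * sqrt(3))
  hc <- init_configuration(state_point(rho_hc, 0.1), 72, "honeycomb", seed = 1)
  d <- rosewater:::config_pair_distances(hc)
  nn <- sapply(seq_len(72), function(i) {
    dx <- rosewater:::min_image(hc$x - hc$x[i], hc$L)
    dy <- rosewater:::min_image(hc$y - hc$y[i], hc$L)
    sum(dx^2 + dy^2 > 0 & dx^2 + dy^2 < 1.2^2)
  })
  expect_true(all(nn == 3))
  # triangular: 6 neighbours within 1.2x the nearest-neighbour spacing
  tr <- init_configuration(state_point(0.9, 0.1), 64, "triangular", seed = 1)
  dt <- rosewater:::config_pair_distances(tr)
  a_nn <- min(dt)
  nn6 <- sapply(seq_len(64), function(i) {
    dx <- rosewater:::min_image(tr$x - tr$x[i], tr$L)
    dy <- rosewater:::min_image(tr$y - tr$y[i], tr$L)
    sum(dx^2 + dy^2 > 0 & dx^2 + dy^2 < (1.2 * a_nn)^2)
  })
  expect_true(all(nn6 == 6))
  expect_error(init_configuration(state_point(0.9, 0.1), 63, "honeycomb"),
               "divisible")
})

test_that("ideal gas accepts every move; frozen lattice rejects uphill", {
  sp <- state_point(0.5, 0.3)
  cfg <- init_configuration(sp, 64, "random", seed = 4)
  out <- mc_cycles(cfg, ideal, sp, tiny_settings(), n_cycles = 50)
  expect_equal(out$acc_trans, 1)
  expect_equal(out$acc_rot, 1)
  # bonded honeycomb, quenched to its local minimum, then T -> 0+:
  # essentially every proposal is uphill and rejected
  hc <- bonded_honeycomb()
  sp_q <- state_point(hc$N / hc$L^2, 0.005)
  quenched <- mc_cycles(hc, mb, sp_q, tiny_settings(), n_cycles = 2000)$config
  spc <- state_point(hc$N / hc$L^2, 1e-10)
  frozen <- mc_cycles(quenched, mb, spc, tiny_settings(seed = 2),
                      n_cycles = 20)
  expect_lt(frozen$acc_trans, 0.05)
})

test_that("accepted move deltas track the total energy exactly", {
  # neighbour-list path (N = 100) from an equilibrated liquid state
  sp <- state_point(0.9, 0.15)
  cfg <- init_configuration(sp, 100, "random", seed = 3)
  pp <- rosewater:::unclass_params(mb)
  rc <- rosewater:::resolve_cutoff(mb, cfg$L)
  eq <- rosewater:::mc_cycles_cpp(cfg$x, cfg$y, cfg$phi, cfg$ux, cfg$uy,
                                  cfg$L, sp$T, pp, rc, 5000L, 0.1, 0.4, 7)
  run <- rosewater:::mc_cycles_cpp(eq$x, eq$y, eq$phi, eq$ux, eq$uy,
                                   cfg$L, sp$T, pp, rc, 5000L, 0.1, 0.4, 8)
  expect_lt(abs(run$energy_final - run$energy_initial - run$delta_sum), 1e-8)
  expect_true(run$used_lists)
  # and the endpoint energies agree with the R brute-force oracle
  end <- raw_config(run$x, run$y, run$phi, cfg$L)
  expect_equal(run$energy_final, brute_force_energy(end, mb),
               tolerance = 1e-10)
})

test_that("two-particle sampling reproduces the Boltzmann radial law", {
  # brute-force path; oracle = r * exp(-beta u_LJ) * <exp(-beta u_HB)>_angles,
  # the angular average factorising into two independent half-bond factors
  L <- 3
  sp <- state_point(2 / L^2, 0.3)
  set.seed(9)
  cfg <- raw_config(c(0.5, 1.5), c(0.5, 0.5), runif(2, -pi, pi), L)
  st <- tiny_settings()
  rc <- rosewater:::resolve_cutoff(mb, L)
  # burn in, then record the pair distance every 5 cycles
  out <- mc_cycles(cfg, mb, sp, st, n_cycles = 2000)
  n_samp <- 6000
  rs <- numeric(n_samp)
  pp <- rosewater:::unclass_params(mb)
  state <- out$config
  raw <- list(x = state$x, y = state$y, phi = state$phi,
              ux = state$ux, uy = state$uy)
  for (k in seq_len(n_samp)) {
    raw <- rosewater:::mc_cycles_cpp(raw$x, raw$y, raw$phi, raw$ux, raw$uy,
                                     L, sp$T, pp, rc, 5L, 0.1, 0.4, 1000 + k)
    dx <- rosewater:::min_image(raw$x[2] - raw$x[1], L)
    dy <- rosewater:::min_image(raw$y[2] - raw$y[1], L)
    rs[k] <- sqrt(dx^2 + dy^2)
  }
  # angular factor: g1(c) = mean over theta of exp(-c * U(theta))
  g1 <- function(cc) {
    th <- seq(0, 2 * pi / 3, length.out = 601)[-601]
    vapply(cc, function(c1) mean(exp(-c1 * angular_U(th, mb))), numeric(1))
  }
  dens <- function(r) {
    ulj <- ifelse(r < rc, lj_pair_energy(r, mb), 0)
    cc <- 0.5 * mb$eps_hb * switching_s(r, mb) / sp$T
    r * exp(-ulj / sp$T) * g1(cc)^2
  }
  edges <- seq(0.4, 1.4, 0.1)
  obs <- hist(rs[rs >= 0.4 & rs < 1.4], breaks = edges, plot = FALSE)$counts
  obs <- obs / sum(obs)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  want <- vapply(seq_along(mids), function(b) {
    rr <- seq(edges[b], edges[b + 1], length.out = 21)
    mean(dens(rr))
  }, numeric(1))
  want <- want / sum(want)
  expect_lt(max(abs(cumsum(obs) - cumsum(want))), 0.05)
})

test_that("ideal-gas run obeys the limit laws", {
  sp <- state_point(0.4, 0.7)
  # coarse RDF bins: a structureless gas needs no radial resolution, and
  # wide bins keep the |g - 1| noise bias in t well below its tolerance
  st <- mc_settings(n_equil_cycles = 500, n_series = 8,
                    cycles_per_series = 5000, rng_seed = 31,
                    sample_interval_cycles = 5, rdf_bin_width = 0.4)
  res <- run_simulation(sp, ideal, st, N = 100)
  m <- res$pooled
  # equation of state P = rho T (exact here: the virial of a gas with no
  # interactions is identically zero, so the inequality is met at zero SE)
  expect_lte(abs(m["mean", "P"] - sp$rho * sp$T), 3 * m["se", "P"] + 1e-12)
  # D* = 2 dmax^2 / 3 per cycle for unit acceptance
  expect_equal(res$acceptance[["trans"]], 1)
  d_expect <- 2 * st$dmax_trans^2 / 3
  # slope estimates from a finite random-walk window scatter beyond their
  # nominal series SE, hence the small relative allowance
  expect_lt(abs(m["mean", "D"] - d_expect), 3 * m["se", "D"] + 0.05 * d_expect)
  # structure: g close to 1 everywhere, t and s2 at zero within noise
  expect_lt(mean(abs(res$rdf$g - 1)), 0.02)
  expect_lt(m["mean", "t"], 3 * m["se", "t"] + 0.05)
  expect_lt(abs(m["mean", "s2"]), 3 * m["se", "s2"] + 0.05)
})

test_that("pseudo-diffusion scales with the proposal amplitude", {
  sp <- state_point(0.4, 0.7)
  st_half <- mc_settings(n_equil_cycles = 200, n_series = 5,
                         cycles_per_series = 2000, rng_seed = 33,
                         dmax_trans = 0.05)
  res_half <- run_simulation(sp, ideal, st_half, N = 100)
  d_expect <- 2 * 0.05^2 / 3
  expect_lt(abs(res_half$pooled["mean", "D"] - d_expect),
            3 * res_half$pooled["se", "D"])
})

test_that("runs are bit-reproducible from the seed", {
  sp <- state_point(0.8, 0.2)
  st <- mc_settings(n_equil_cycles = 1000, n_series = 3,
                    cycles_per_series = 1000, rng_seed = 77)
  r1 <- run_simulation(sp, mb, st, N = 100)
  r2 <- run_simulation(sp, mb, st, N = 100)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$pooled, r2$pooled)
  expect_identical(r1$config$x, r2$config$x)
})

test_that("liquid-state run is physically sane (MB preset)", {
  sp <- state_point(0.9, 0.15)
  st <- mc_settings(n_equil_cycles = 10000, n_series = 5,
                    cycles_per_series = 3000, rng_seed = 5)
  res <- run_simulation(sp, mb, st, N = 100)
  expect_lt(res$pooled["mean", "u_per_n"], 0)
  expect_gt(res$pooled["mean", "hb"], 0)
  expect_lt(res$pooled["mean", "hb"], 3)
  # dominant RDF peak sits at the hydrogen-bond distance
  peak <- res$rdf$r[which.max(res$rdf$g)]
  expect_gt(peak, 0.8)
  expect_lt(peak, 1.2)
})

test_that("pure-LJ pressure follows the second-virial law at low density", {
  plj <- rose_parameters("mb", eps_hb = 0)
  sp <- state_point(0.05, 0.5)
  st <- mc_settings(n_equil_cycles = 2000, n_series = 8,
                    cycles_per_series = 4000, rng_seed = 13,
                    sample_interval_cycles = 20)
  res <- run_simulation(sp, plj, st, N = 100)
  rc <- res$r_cut
  rr <- seq(1e-4, rc, length.out = 4001)
  b2 <- -pi * rosewater:::trapz(rr, (exp(-lj_pair_energy(rr, plj) / sp$T) - 1) * rr)
  p_virial <- sp$rho * sp$T * (1 + b2 * sp$rho)
  expect_lt(abs(res$pooled["mean", "P"] - p_virial),
            3 * res$pooled["se", "P"] + 1e-4)
})

test_that("virial pressure and D* helpers satisfy their contracts", {
  sp <- state_point(0.5, 0.3)
  expect_equal(virial_pressure(numeric(5), sp, 100), 0.15)
  expect_equal(pseudo_diffusion(list(cycle = 1:100, msd = rep(2, 100))), 0)
  expect_error(pseudo_diffusion(list(cycle = 1:5, msd = 1:5)), "10")
  # exact slope recovery on a linear curve
  expect_equal(pseudo_diffusion(list(cycle = 1:50, msd = 0.3 * (1:50))), 0.3)
})

test_that("dmax auto-adjustment drives acceptance toward its target", {
  sp <- state_point(0.9, 0.15)
  st <- mc_settings(n_equil_cycles = 20000, n_series = 2,
                    cycles_per_series = 500, rng_seed = 3,
                    dmax_trans = 0.9, adjust_dmax = TRUE)
  res <- run_simulation(sp, mb, st, N = 100)
  expect_lt(res$dmax_used[["trans"]], 0.9)   # shrunk from the poor start
  expect_gt(res$acceptance[["trans"]], 0.2)
  expect_lt(res$acceptance[["trans"]], 0.6)
})
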