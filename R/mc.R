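#' Monte Carlo run settings
#'
#' Bundles the NVT Metropolis protocol: equilibration length, production
#' series structure, proposal maxima, and sampling intervals.  One cycle is
#' `N` translation attempts plus `N` rotation attempts, each on an
#' independently drawn random particle, so on average every molecule is
#' translated and rotated once per cycle.
#'
#' Three profiles bundle the cycle counts: `"desk"` (1e5 equilibration
#' cycles, 10 series of 2e4) for a single state point, `"scan"` (2e4
#' equilibration, 10 series of 3e3, structural sampling every 40 cycles)
#' for density-temperature grids of hundreds of points, and `"paper"`
#' (1e6 equilibration, 20 series of 1e6) for full-scale statistics.
#'
#' @param n_equil_cycles Equilibration cycles.
#' @param n_series Number of production series (block means; standard errors
#'   are computed over these).
#' @param cycles_per_series Cycles per production series.
#' @param dmax_trans Maximum translation displacement per axis, `r_hb` units.
#' @param dmax_rot Maximum rotation step, radians, in `(0, pi]`.
#' @param adjust_dmax If `TRUE`, the proposal maxima are driven toward ~40%
#'   acceptance during equilibration, then frozen for production.  Off by
#'   default: comparisons of the pseudo-diffusion coefficient across state
#'   points require a common, fixed proposal scale.
#' @param sample_interval_cycles Cycles between structural/thermodynamic
#'   samples.
#' @param msd_interval_cycles Cycles between mean-square-displacement records.
#' @param rdf_bin_width RDF bin width, `r_hb` units.
#' @param shell_cutoff First-shell neighbour cutoff for the orientational
#'   order parameters (position of the first RDF minimum after the HB peak).
#' @param hb_threshold Half-bond energy threshold, in `eps_hb` units: a half
#'   bond exists when its energy is below `hb_threshold`, a full bond when
#'   both halves are.
#' @param rng_seed Integer seed; fixes the whole trajectory.
#' @param store_frames Keep the end-of-series configurations in the result.
#' @param profile `"desk"`, `"scan"` or `"paper"`: shorthand for the cycle
#'   counts.  `"desk"` (the default) suits a single state point; `"scan"` is
#'   the lighter per-point protocol used for density-temperature grid scans,
#'   where hundreds of state points share the budget; `"paper"` is the
#'   full-scale protocol.
#' @return An object of class `"mc_settings"`.
#' @export
mc_settings <- function(n_equil_cycles = NULL, n_series = NULL,
                        cycles_per_series = NULL,
                        dmax_trans = 0.1, dmax_rot = 0.4,
                        adjust_dmax = FALSE,
                        sample_interval_cycles = 100,
                        msd_interval_cycles = 10,
                        rdf_bin_width = 0.02, shell_cutoff = 1.2,
                        hb_threshold = -0.125,
                        rng_seed = 1L, store_frames = FALSE,
                        profile = c("desk", "scan", "paper")) {
  profile <- match.arg(profile)
  prof <- switch(profile,
    paper = list(n_equil_cycles = 1e6, n_series = 20, cycles_per_series = 1e6),
    scan  = list(n_equil_cycles = 2e4, n_series = 10, cycles_per_series = 3e3),
    desk  = list(n_equil_cycles = 1e5, n_series = 10, cycles_per_series = 2e4))
  if (profile == "scan" && missing(sample_interval_cycles)) {
    sample_interval_cycles <- 40
  }
  s <- list(
    n_equil_cycles = as.integer(n_equil_cycles %||% prof$n_equil_cycles),
    n_series = as.integer(n_series %||% prof$n_series),
    cycles_per_series = as.integer(cycles_per_series %||% prof$cycles_per_series),
    dmax_trans = dmax_trans, dmax_rot = dmax_rot,
    adjust_dmax = isTRUE(adjust_dmax),
    sample_interval_cycles = as.integer(sample_interval_cycles),
    msd_interval_cycles = as.integer(msd_interval_cycles),
    rdf_bin_width = rdf_bin_width, shell_cutoff = shell_cutoff,
    hb_threshold = hb_threshold,
    rng_seed = as.integer(rng_seed), store_frames = isTRUE(store_frames))
  stopifnot(s$n_equil_cycles >= 0, s$n_series >= 1, s$cycles_per_series >= 1,
            s$sample_interval_cycles >= 1, s$msd_interval_cycles >= 1,
            s$dmax_trans > 0, s$dmax_rot > 0, s$dmax_rot <= pi,
            s$rdf_bin_width > 0, s$shell_cutoff > 0, s$hb_threshold <= 0)
  structure(s, class = "mc_settings")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run Monte Carlo cycles on a configuration
#'
#' Advances a configuration by `n_cycles` cycles (each `N` translation plus
#' `N` rotation attempts with Metropolis acceptance `min(1, exp(-dU/T))`) and
#' returns the updated configuration with acceptance statistics.  Accepted
#' translations increment the unwrapped displacement accumulators.
#'
#' @param config A `rose_configuration`.
#' @param p A [rose_parameters()] object.
#' @param sp A [state_point()] (temperature is taken from here; the density
#'   is fixed by the configuration).
#' @param settings An [mc_settings()] object (proposal maxima and seed).
#' @param n_cycles Number of cycles to run.
#' @return List with `config` (updated), `acc_trans`, `acc_rot`.
#' @export
mc_cycles <- function(config, p, sp, settings, n_cycles = 1L) {
  stopifnot(inherits(config, "rose_configuration"),
            inherits(sp, "state_point"), inherits(settings, "mc_settings"))
  rc <- resolve_cutoff(p, config$L)
  out <- mc_cycles_cpp(config$x, config$y, config$phi, config$ux, config$uy,
                       config$L, sp$T, unclass_params(p), rc,
                       as.integer(n_cycles),
                       settings$dmax_trans, settings$dmax_rot,
                       as.double(settings$rng_seed))
  config$x <- out$x; config$y <- out$y; config$phi <- out$phi
  config$ux <- out$ux; config$uy <- out$uy
  list(config = config, acc_trans = out$acc_trans, acc_rot = out$acc_rot)
}

#' Virial pressure in two dimensions
#'
#' \eqn{P = \rho T - \langle \sum_{i<j} r_{ij} u'(r_{ij}) \rangle / (2A)}
#' with `A = L^2` the box area.  The virial sum uses the radial derivative of
#' the pair potential at fixed orientations ([pair_radial_virial()]).
#'
#' @param w_samples Samples of the pair virial sum \eqn{\sum r u'(r)}.
#' @param sp A [state_point()].
#' @param area Box area `L^2`.
#' @return Pressure in reduced units.
#' @export
virial_pressure <- function(w_samples, sp, area) {
  stopifnot(inherits(sp, "state_point"), area > 0, length(w_samples) >= 1)
  sp$rho * sp$T - mean(w_samples) / (2 * area)
}

#' Pseudo-diffusion coefficient from a mean-square-displacement curve
#'
#' \eqn{D^* = \lim_{n\to\infty} \langle \Delta r^2(n) \rangle / n}, estimated
#' as the least-squares slope of the MSD versus cycle index over the second
#' half of the recorded window (the early part of the curve carries the
#' ballistic-like transient of the proposal scale).  Valid only for runs with
#' a fixed maximum displacement.
#'
#' @param msd_curve Data frame (or list) with components `cycle` and `msd`.
#' @return Slope \eqn{D^*} (displacement^2 per cycle).
#' @export
pseudo_diffusion <- function(msd_curve) {
  cyc <- msd_curve$cycle
  msd <- msd_curve$msd
  stopifnot(length(cyc) == length(msd))
  if (length(cyc) < 10L) stop("need at least 10 MSD points to fit D*")
  keep <- seq.int(ceiling(length(cyc) / 2), length(cyc))
  x <- cyc[keep]; ym <- msd[keep]
  unname(stats::cov(x, ym) / stats::var(x))
}

#' Run a full NVT Monte Carlo simulation at one state point
#'
#' Equilibrates, freezes the proposal maxima, then runs the production series
#' and collects the observable suite: energy per particle, virial pressure,
#' radial distribution function, translational order parameter `t`,
#' orientational order `q3`/`q6`, pair entropy `s2`, hydrogen-bond count per
#' molecule, the MSD curve and the pseudo-diffusion coefficient `D*`.  All
#' uncertainties are standard errors over the production-series block means.
#' Fully reproducible from `settings$rng_seed`.
#'
#' @param sp A [state_point()].
#' @param p A [rose_parameters()] object.
#' @param settings An [mc_settings()] object.
#' @param N Particle count (box side follows from the density).
#' @param config Optional starting `rose_configuration`; by default a fresh
#'   random configuration is drawn from `settings$rng_seed`.
#' @return An object of class `"rose_run_result"`: list with `state`,
#'   `series` (per-series data frame), `pooled` (named rows `mean`/`se`),
#'   `rdf` (`r`, `g`, per-series matrix), `msd` (`cycle`, pooled curve,
#'   per-series matrix), final `config`, acceptance rates and the frozen
#'   proposal maxima.
#' @examples
#' \donttest{
#' p <- rose_parameters("mb")
#' st <- mc_settings(n_equil_cycles = 2000, n_series = 4,
#'                   cycles_per_series = 2000, rng_seed = 7)
#' res <- run_simulation(state_point(0.9, 0.20), p, st, N = 64)
#' res$pooled["mean", "P"]
#' }
#' @export
run_simulation <- function(sp, p, settings, N = 100L, config = NULL) {
  stopifnot(inherits(sp, "state_point"), inherits(p, "rose_parameters"),
            inherits(settings, "mc_settings"))
  if (is.null(config)) {
    config <- init_configuration(sp, N, mode = "random",
                                 seed = settings$rng_seed)
  } else {
    stopifnot(inherits(config, "rose_configuration"))
    N <- config$N
  }
  if (abs(config$N / config$L^2 - sp$rho) > 1e-8 * sp$rho) {
    stop("configuration density does not match the state point")
  }
  rc <- resolve_cutoff(p, config$L)
  cs <- settings
  cs$hb_threshold <- settings$hb_threshold * p$eps_hb
  cs$seed <- as.double(settings$rng_seed)
  raw <- run_rose_mc_cpp(config$x, config$y, config$phi, config$L, sp$T,
                         unclass_params(p), rc, cs)

  ns <- settings$n_series
  area <- config$L^2
  ser <- as.data.frame(raw$series)
  ser$series <- seq_len(ns)
  ser$P <- sp$rho * sp$T - ser$w_sum / (2 * area)

  # per-series RDF, t and s2
  nb <- raw$nbins
  db <- raw$rdf_bin_width
  edges <- db * (0:nb)
  mid <- (edges[-1] + edges[-(nb + 1)]) / 2
  annulus <- pi * (edges[-1]^2 - edges[-(nb + 1)]^2)
  g_series <- matrix(0, ns, nb)
  for (s in seq_len(ns)) {
    g_series[s, ] <- 2 * raw$rdf_counts[s, ] /
      (ser$n_samples[s] * N * sp$rho * annulus)
  }
  mk_rdf <- function(g) {
    structure(list(r = mid, g = g, bin_width = db, rho = sp$rho,
                   r_c = config$L / 2), class = "rose_rdf")
  }
  ser$t <- apply(g_series, 1, function(g) translational_order(mk_rdf(g)))
  ser$s2 <- apply(g_series, 1, function(g) pair_entropy(mk_rdf(g)))

  # per-series D* from the series MSD curves
  msd_cycles <- settings$msd_interval_cycles *
    seq_len(ncol(raw$msd))
  ser$D <- apply(raw$msd, 1, function(m)
    pseudo_diffusion(list(cycle = msd_cycles, msd = m)))

  obs <- c("u_per_n", "P", "t", "q3", "q6", "s2", "hb", "D")
  pooled <- rbind(mean = vapply(ser[obs], mean, numeric(1)),
                  se = vapply(ser[obs], stats::sd, numeric(1)) / sqrt(ns))
  pooled <- as.data.frame(pooled)

  config$x <- raw$x; config$y <- raw$y; config$phi <- raw$phi
  config$ux <- raw$ux; config$uy <- raw$uy

  structure(list(
    state = sp, params = p, settings = settings, N = N,
    series = ser, pooled = pooled,
    rdf = mk_rdf(colMeans(g_series)),
    rdf_series = g_series,
    msd = list(cycle = msd_cycles, msd = colMeans(raw$msd)),
    msd_series = raw$msd,
    config = config,
    frames = raw$frames,
    acceptance = c(trans = mean(ser$acc_trans), rot = mean(ser$acc_rot)),
    dmax_used = c(trans = raw$dmax_trans_used, rot = raw$dmax_rot_used),
    r_cut = raw$r_cut, used_cells = raw$used_cells),
    class = "rose_run_result")
}

#' @export
print.rose_run_result <- function(x, ...) {
  cat(sprintf("rose MC run: N = %d, rho = %g, T* = %g (%d series)\n",
              x$N, x$state$rho, x$state$T, nrow(x$series)))
  m <- x$pooled
  for (o in colnames(m)) {
    cat(sprintf("  %-7s %12.6f +/- %.6f\n", o, m["mean", o], m["se", o]))
  }
  cat(sprintf("  acceptance: trans %.3f, rot %.3f (dmax %.3g / %.3g)\n",
              x$acceptance["trans"], x$acceptance["rot"],
              x$dmax_used["trans"], x$dmax_used["rot"]))
  invisible(x)
}
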