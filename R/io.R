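#' Load and validate a run configuration file
#'
#' Reads a YAML run configuration with blocks `model` (preset name or
#' explicit potential parameters), `state` (`rho`/`T` scalars or `rho_grid`/
#' `T_grid`), `mc` ([mc_settings()] fields) and `output`.  Unknown keys and
#' contradictory specifications (both a preset and a full explicit parameter
#' set) are rejected with an itemised error.  The resolved configuration
#' round-trips unchanged through [write_run_config()].
#'
#' @param path Path to a YAML file.
#' @return An object of class `"rose_run_config"`: list with `model` (a
#'   [rose_parameters()] object), `state`, `mc` (an [mc_settings()] object),
#'   `N`, `output`, and `schema_version`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  errs <- character(0)
  top_known <- c("schema_version", "model", "state", "mc", "output",
                 "n_particles")
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown top-level key(s): ",
                           paste(unknown, collapse = ", ")))
  }
  model <- raw[["model"]] %||% list(preset = "mb")
  par_fields <- c("eps_lj", "sigma_lj", "eps_hb", "r_hb", "r_fwhm",
                  "a1", "a2", "r_cut")
  m_unknown <- setdiff(names(model), c("preset", par_fields))
  if (length(m_unknown)) {
    errs <- c(errs, paste0("unknown model key(s): ",
                           paste(m_unknown, collapse = ", ")))
  }
  explicit <- intersect(names(model), setdiff(par_fields, "r_cut"))
  if (!is.null(model$preset) && length(explicit) == length(par_fields) - 1) {
    errs <- c(errs, "model gives both a preset and a full explicit parameter set")
  }
  state <- raw[["state"]] %||% list()
  s_unknown <- setdiff(names(state), c("rho", "T", "rho_grid", "T_grid"))
  if (length(s_unknown)) {
    errs <- c(errs, paste0("unknown state key(s): ",
                           paste(s_unknown, collapse = ", ")))
  }
  if (!is.null(state[["rho"]]) && !is.null(state[["rho_grid"]])) {
    errs <- c(errs, "state gives both rho and rho_grid")
  }
  mc <- raw[["mc"]] %||% list()
  mc_known <- c("n_equil_cycles", "n_series", "cycles_per_series",
                "dmax_trans", "dmax_rot", "adjust_dmax",
                "sample_interval_cycles", "msd_interval_cycles",
                "rdf_bin_width", "shell_cutoff", "hb_threshold",
                "rng_seed", "store_frames", "profile")
  c_unknown <- setdiff(names(mc), mc_known)
  if (length(c_unknown)) {
    errs <- c(errs, paste0("unknown mc key(s): ",
                           paste(c_unknown, collapse = ", ")))
  }
  if (length(errs)) {
    stop("invalid run config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  params <- do.call(rose_parameters, c(list(preset = model[["preset"]]),
                                       model[setdiff(names(model), "preset")]))
  settings <- do.call(mc_settings, mc)
  structure(list(
    schema_version = raw[["schema_version"]] %||% 1L,
    model = params,
    state = state,
    mc = settings,
    N = as.integer(raw[["n_particles"]] %||% 100L),
    output = raw[["output"]] %||% list()),
    class = "rose_run_config")
}

#' Serialize a run configuration back to YAML
#'
#' @param config A `"rose_run_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "rose_run_config"))
  p <- config$model
  model <- if (!is.na(p$preset)) list(preset = p$preset) else
    list(eps_lj = p$eps_lj, sigma_lj = p$sigma_lj, eps_hb = p$eps_hb,
         r_hb = p$r_hb, r_fwhm = p$r_fwhm, a1 = p$a1, a2 = p$a2)
  if (!is.na(p$r_cut)) model$r_cut <- p$r_cut
  mc <- unclass(config$mc)
  yaml::write_yaml(list(schema_version = config$schema_version,
                        model = model, state = config$state,
                        n_particles = config$N, mc = mc,
                        output = config$output),
                   path)
  invisible(path)
}

#' Write trajectory frames as extended-XYZ-style text
#'
#' One block per frame: a count line, a comment line carrying `L`, `rho`,
#' `T` and the cycle index, then one `x y phi` line per particle (full
#' double precision).  [read_frames()] inverts this exactly.
#'
#' @param frames A `rose_configuration` or list of them.
#' @param path Output path.
#' @param sp Optional [state_point()] recorded on the comment lines.
#' @param cycles Optional cycle indices (recycled along frames).
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, sp = NULL, cycles = NULL) {
  if (inherits(frames, "rose_configuration")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  cycles <- if (is.null(cycles)) rep(NA_integer_, length(frames))
            else rep_len(cycles, length(frames))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    writeLines(as.character(f$N), con)
    writeLines(sprintf(
      "L=%.17g rho=%.17g T=%.17g cycle=%s columns=x:y:phi",
      f$L, f$N / f$L^2,
      if (is.null(sp)) NA_real_ else sp$T,
      format(cycles[k])), con)
    writeLines(sprintf("%.17g %.17g %.17g", f$x, f$y, f$phi), con)
  }
  invisible(path)
}

#' Read trajectory frames written by [write_frames()]
#'
#' @param path Path to the frames file.
#' @return List of `rose_configuration` objects (empty list for an empty
#'   file).  Malformed blocks raise an error naming the offending line.
#' @export
read_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      stop(sprintf("line %d: expected a particle count", i))
    }
    n <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    Lm <- regmatches(hdr, regexec("L=([-0-9.eE+]+)", hdr))[[1]]
    if (length(Lm) < 2) stop(sprintf("line %d: missing L= in header", i + 1L))
    L <- as.numeric(Lm[2])
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) != 3L)
    if (length(bad)) {
      stop(sprintf("line %d: expected 3 columns (x y phi)", i + 1L + bad[1]))
    }
    m <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
    if (anyNA(m)) stop(sprintf("frame starting at line %d: non-numeric field", i))
    frames[[length(frames) + 1L]] <- structure(
      list(N = n, L = L, x = m[, 1], y = m[, 2], phi = m[, 3],
           ux = numeric(n), uy = numeric(n)),
      class = "rose_configuration")
    i <- i + 2L + n
  }
  frames
}

#' Brute-force total energy (reference oracle)
#'
#' Plain double loop over all distinct pairs with the minimum-image
#' convention and the same cutoff policy as the engine, built solely on the
#' R-level pair potential.  This is the reference that the compiled engine
#' is checked against.
#'
#' @param config A `rose_configuration`.
#' @param p A [rose_parameters()] object.
#' @return Total potential energy in `eps_hb` units.
#' @export
brute_force_energy <- function(config, p) {
  stopifnot(inherits(config, "rose_configuration"))
  rc <- resolve_cutoff(p, config$L)
  e <- 0
  N <- config$N
  if (N < 2) return(0)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      dx <- min_image(config$x[j] - config$x[i], config$L)
      dy <- min_image(config$y[j] - config$y[i], config$L)
      if (dx * dx + dy * dy < rc^2) {
        e <- e + pair_energy(c(config$x[i], config$y[i], config$phi[i]),
                             c(config$x[j], config$y[j], config$phi[j]),
                             p, box = config$L)
      }
    }
  }
  e
}

#' Deterministic per-run seeds from a master seed
#'
#' Collision-free within a master seed: distinct state-point indices map to
#' distinct seeds (an affine map modulo the prime 2147483629), all below
#' 2^31.
#'
#' @param master_seed Integer master seed.
#' @param statepoint_index Positive integer index (vectorised).
#' @return Integer seed(s) in `[1, 2147483628]`.
#' @export
seed_manager <- function(master_seed, statepoint_index) {
  p <- 2147483629
  s <- (as.numeric(master_seed) %% p) * 69069 + as.numeric(statepoint_index) * 7919
  as.integer(s %% p + 1)
}

#' Write per-state-point scan results as tidy CSV
#'
#' @param scan A `"rose_grid_scan"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "rose_grid_scan"))
  utils::write.csv(scan$points, path, row.names = FALSE)
  invisible(path)
}
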