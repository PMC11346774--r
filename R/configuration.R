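#' Thermodynamic state point
#'
#' Reduced number density \eqn{\rho = N/L^2} (in \eqn{r_{HB}^{-2}}) and
#' reduced temperature \eqn{T^* = k_B T / |\epsilon_{HB}|} (with
#' \eqn{k_B = 1}).
#'
#' @param rho Number density, `> 0`.
#' @param T Reduced temperature, `> 0`.
#' @return An object of class `"state_point"`.
#' @export
state_point <- function(rho, T) {
  stopifnot(rho > 0, T > 0)
  structure(list(rho = as.numeric(rho), T = as.numeric(T)),
            class = "state_point")
}

#' @export
print.state_point <- function(x, ...) {
  cat(sprintf("state point: rho = %g, T* = %g\n", x$rho, x$T))
  invisible(x)
}

#' Initial configuration of rose particles
#'
#' Places `N` particles in a periodic square box whose side is chosen so that
#' `N / L^2` equals the requested density exactly.  Orientations are always
#' uniform on `[-pi, pi)`.
#'
#' Modes:
#' \describe{
#'   \item{`"random"`}{Uniform positions (simulations start here, as dense
#'     starts are resolved during equilibration).}
#'   \item{`"triangular"`}{Perfect triangular lattice; requires `N = 2 m k`
#'     with the `m x k` rectangular pattern closest to square (rows of 2
#'     particles per cell).}
#'   \item{`"honeycomb"`}{Honeycomb lattice (each site 3-coordinated);
#'     requires `N = 4 m k`.}
#' }
#'
#' @param sp A [state_point()] (only `rho` is used).
#' @param N Particle count.
#' @param mode `"random"`, `"triangular"` or `"honeycomb"`.
#' @param seed Optional integer seed for R's RNG (local to this call).
#' @return An object of class `"rose_configuration"`: list with `N`, `L`,
#'   numeric vectors `x`, `y` (wrapped to `[0, L)`), `phi`, and unwrapped
#'   displacement accumulators `ux`, `uy` (zeroed).
#' @examples
#' cfg <- init_configuration(state_point(0.9, 0.15), N = 64, mode = "random",
#'                           seed = 1)
#' cfg$L^2 * 0.9 # = 64
#' @export
init_configuration <- function(sp, N, mode = c("random", "triangular",
                                               "honeycomb"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(sp, "state_point"), N >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  L <- sqrt(N / sp$rho)
  if (mode == "random") {
    x <- stats::runif(N, 0, L)
    y <- stats::runif(N, 0, L)
  } else {
    basis <- if (mode == "triangular") {
      # 2-particle rectangular cell of a triangular lattice, aspect sqrt(3)
      list(n_basis = 2L, bx = c(0, 0.5), by = c(0, 0.5), aspect = sqrt(3))
    } else {
      # 4-particle rectangular cell of a honeycomb lattice
      list(n_basis = 4L, bx = c(0, 0.5, 0.5, 0), by = c(0, 1 / 6, 0.5, 2 / 3),
           aspect = sqrt(3))
    }
    nb <- basis$n_basis
    if (N %% nb != 0L) {
      stop(sprintf("%s lattice needs N divisible by %d", mode, nb))
    }
    ncell <- N %/% nb
    # m x k cell grid with m/k as close as possible to the cell aspect ratio
    divs <- which(ncell %% seq_len(ncell) == 0L)
    m <- divs[which.min(abs(log(divs^2 / (ncell * basis$aspect))))]
    k <- ncell %/% m
    ax <- L / m  # cell width  (m cells across)
    ay <- L / k  # cell height (k cells up)
    ij <- expand.grid(i = seq_len(m) - 1L, j = seq_len(k) - 1L)
    x <- as.vector(outer(ij$i, basis$bx, "+")) * ax
    y <- rep(ij$j, times = nb) * ay + rep(basis$by, each = nrow(ij)) * ay
    x <- x %% L
    y <- y %% L
  }
  phi <- stats::runif(N, -pi, pi)
  structure(list(N = as.integer(N), L = L, x = x, y = y, phi = phi,
                 ux = numeric(N), uy = numeric(N)),
            class = "rose_configuration")
}

#' @export
print.rose_configuration <- function(x, ...) {
  cat(sprintf("rose configuration: N = %d, L = %.4f (rho = %.4f)\n",
              x$N, x$L, x$N / x$L^2))
  invisible(x)
}

# all-pairs minimum-image distances of a configuration (helper for small-N
# analysis paths; O(N^2))
config_pair_distances <- function(config) {
  dx <- outer(config$x, config$x, "-")
  dy <- outer(config$y, config$y, "-")
  dx <- min_image(dx, config$L)
  dy <- min_image(dy, config$L)
  d <- sqrt(dx^2 + dy^2)
  d[upper.tri(d)]
}
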