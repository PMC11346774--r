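#' Locate significant interior extrema of a noisy curve
#'
#' An interior point is reported as an extremum when the discrete derivative
#' changes sign there and the extremal mean differs from both flanking means
#' by more than `k` times the combined standard error.  The location is
#' refined by a three-point parabolic fit through the extremum and its
#' flanks.
#'
#' @param x Strictly increasing abscissa values (at least 5).
#' @param y Means at `x`.
#' @param se Standard errors of `y` (zeros allowed for noiseless input).
#' @param kind `"min"` or `"max"`.
#' @param k Significance multiplier on the combined SE (default 1).
#' @return Data frame with columns `x` (refined location), `y` (parabola
#'   vertex value), `index` (grid index of the extremal point); zero rows if
#'   none found.
#' @export
find_extrema <- function(x, y, se = NULL, kind = c("min", "max"), k = 1) {
  kind <- match.arg(kind)
  n <- length(x)
  stopifnot(length(y) == n, n >= 5)
  if (is.unsorted(x, strictly = TRUE)) stop("x must be strictly increasing")
  if (is.null(se)) se <- numeric(n)
  sgn <- if (kind == "min") -1 else 1
  out <- list()
  for (i in 2:(n - 1)) {
    dl <- y[i] - y[i - 1]
    dr <- y[i + 1] - y[i]
    if (!(sgn * dl > 0 && sgn * dr < 0)) next
    if (abs(dl) <= k * sqrt(se[i]^2 + se[i - 1]^2)) next
    if (abs(dr) <= k * sqrt(se[i]^2 + se[i + 1]^2)) next
    v <- refine_parabola(x[(i - 1):(i + 1)], y[(i - 1):(i + 1)])
    out[[length(out) + 1L]] <- data.frame(x = v[1], y = v[2], index = i)
  }
  if (length(out) == 0) {
    data.frame(x = numeric(0), y = numeric(0), index = integer(0))
  } else {
    do.call(rbind, out)
  }
}

# vertex of the parabola through three points; falls back to the middle
# point when the three are collinear
refine_parabola <- function(x3, y3) {
  d21 <- x3[2] - x3[1]; d23 <- x3[2] - x3[3]
  num <- d21^2 * (y3[2] - y3[3]) - d23^2 * (y3[2] - y3[1])
  den <- d21 * (y3[2] - y3[3]) - d23 * (y3[2] - y3[1])
  if (den == 0) return(c(x3[2], y3[2]))
  xv <- x3[2] - 0.5 * num / den
  # evaluate the Lagrange parabola at the vertex
  l <- function(xx) {
    y3[1] * (xx - x3[2]) * (xx - x3[3]) / ((x3[1] - x3[2]) * (x3[1] - x3[3])) +
    y3[2] * (xx - x3[1]) * (xx - x3[3]) / ((x3[2] - x3[1]) * (x3[2] - x3[3])) +
    y3[3] * (xx - x3[1]) * (xx - x3[2]) / ((x3[3] - x3[1]) * (x3[3] - x3[2]))
  }
  c(xv, l(xv))
}

new_anomaly_region <- function(kind, points, scan = NULL) {
  if (nrow(points) == 0L) {
    points <- data.frame(rho = numeric(0), T = numeric(0), P = numeric(0))
  }
  points <- points[order(points$T, points$rho), , drop = FALSE]
  structure(list(kind = kind, points = points,
                 max_temperature = if (nrow(points)) max(points$T) else NA_real_,
                 empty = nrow(points) == 0L),
            class = "anomaly_region")
}

#' @export
print.anomaly_region <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("anomaly region [%s]: empty\n", x$kind))
  } else {
    cat(sprintf("anomaly region [%s]: %d boundary points, max T = %.4g\n",
                x$kind, nrow(x$points), x$max_temperature))
  }
  invisible(x)
}

scan_points <- function(scan) {
  if (inherits(scan, "rose_grid_scan")) scan$points else as.data.frame(scan)
}

#' Density anomaly (TMD) locus
#'
#' The temperature of maximum density at constant pressure coincides with the
#' temperature of the pressure minimum at constant density, so the locus is
#' assembled by scanning pressure versus temperature at each density for
#' significant minima.
#'
#' @param scan A grid scan (see [run_grid_scan()]) or a data frame with
#'   columns `rho`, `T`, `P`, `P_se`.
#' @param k Significance multiplier for [find_extrema()].
#' @return An `"anomaly_region"` of kind `"density"` whose points are the
#'   detected `(rho, T, P)` pressure minima; `max_temperature` is the highest
#'   detected minimum temperature.
#' @export
density_anomaly_locus <- function(scan, k = 1) {
  pts <- scan_points(scan)
  out <- data.frame()
  for (r in sort(unique(pts$rho))) {
    sub <- pts[pts$rho == r, ]
    sub <- sub[order(sub$T), ]
    if (nrow(sub) < 5) next
    ex <- find_extrema(sub$T, sub$P, sub$P_se, "min", k = k)
    if (nrow(ex) == 0) next
    best <- ex[which.min(ex$y), ]
    out <- rbind(out, data.frame(rho = r, T = best$x, P = best$y))
  }
  new_anomaly_region("density", out)
}

# shared min-then-max (or max-then-min) pairing along density at fixed T
paired_extrema_region <- function(scan, col, kind,
                                  direction = c("min_max", "max_min"),
                                  k = 1, first_only = FALSE) {
  direction <- match.arg(direction)
  pts <- scan_points(scan)
  se_col <- paste0(col, "_se")
  out <- data.frame()
  for (Tv in sort(unique(pts$T))) {
    sub <- pts[pts$T == Tv, ]
    sub <- sub[order(sub$rho), ]
    if (nrow(sub) < 5) next
    lo_kind <- if (direction == "min_max") "min" else "max"
    hi_kind <- if (direction == "min_max") "max" else "min"
    lo <- find_extrema(sub$rho, sub[[col]], sub[[se_col]], lo_kind, k = k)
    hi <- find_extrema(sub$rho, sub[[col]], sub[[se_col]], hi_kind, k = k)
    if (nrow(lo) == 0 || nrow(hi) == 0) next
    lo1 <- lo[1, ]
    hi1 <- hi[hi$x > lo1$x, ]
    if (nrow(hi1) == 0) next
    hi1 <- hi1[1, ]
    if (first_only) { lo1 <- lo[1, ] }  # first pair scanning from low rho
    pcol <- if ("P" %in% names(sub)) {
      stats::approx(sub$rho, sub$P, xout = c(lo1$x, hi1$x), rule = 2)$y
    } else c(NA_real_, NA_real_)
    out <- rbind(out,
      data.frame(rho = c(lo1$x, hi1$x), T = Tv, P = pcol,
                 side = c("low", "high"), value = c(lo1$y, hi1$y)))
  }
  new_anomaly_region(kind, out)
}

#' Diffusion anomaly region
#'
#' At fixed temperature a normal fluid's diffusion coefficient decreases
#' monotonically with density; inside the anomaly the pseudo-diffusion
#' coefficient `D*` passes through a local minimum and then a local maximum
#' as density grows.  The region spans the densities between the paired
#' extrema at each temperature where the pair is detected.
#'
#' @inheritParams density_anomaly_locus
#' @return An `"anomaly_region"` of kind `"diffusion"` with the paired
#'   extremum locations as boundary points (`side` column: `"low"`/`"high"`).
#' @export
diffusion_anomaly_region <- function(scan, k = 1) {
  paired_extrema_region(scan, "D", "diffusion", "min_max", k = k)
}

#' Structural anomaly region
#'
#' For the translational order parameter `t` the anomaly is where order
#' decreases on compression: a local maximum of `t(rho)` followed by a local
#' minimum.  For the pair entropy `s2` the anomaly is where entropy increases
#' on compression: a local minimum followed by a local maximum.
#'
#' @inheritParams density_anomaly_locus
#' @param observable `"t"` or `"s2"`.
#' @return An `"anomaly_region"` of kind `"structural_t"` or `"entropy"`.
#' @export
structural_anomaly_region <- function(scan, observable = c("t", "s2"),
                                      k = 1) {
  observable <- match.arg(observable)
  if (observable == "t") {
    paired_extrema_region(scan, "t", "structural_t", "max_min", k = k)
  } else {
    paired_extrema_region(scan, "s2", "entropy", "min_max", k = k)
  }
}

#' Maxima of the bond-orientational order parameters along density
#'
#' Locates local maxima of `q3` or `q6` versus density on each isotherm.
#' With `first_only = TRUE` only the lowest-density maximum is kept (the
#' six-fold parameter of the real parametrisation develops a second rise at
#' high density, and only the first peak defines the locus).
#'
#' @inheritParams density_anomaly_locus
#' @param l 3 or 6.
#' @param first_only Keep only the first maximum scanning from low density.
#' @return An `"anomaly_region"` of kind `"orientational_q3"` or
#'   `"orientational_q6"`.
#' @export
orientational_maxima <- function(scan, l = 3, first_only = (l == 6), k = 1) {
  stopifnot(l %in% c(3, 6))
  col <- paste0("q", l)
  pts <- scan_points(scan)
  out <- data.frame()
  for (Tv in sort(unique(pts$T))) {
    sub <- pts[pts$T == Tv, ]
    sub <- sub[order(sub$rho), ]
    if (nrow(sub) < 5) next
    mx <- find_extrema(sub$rho, sub[[col]], sub[[paste0(col, "_se")]],
                       "max", k = k)
    if (nrow(mx) == 0) next
    if (first_only) mx <- mx[1, , drop = FALSE]
    out <- rbind(out, data.frame(rho = mx$x, T = Tv, P = NA_real_,
                                 value = mx$y))
  }
  new_anomaly_region(paste0("orientational_q", l), out)
}

# polygon area (shoelace) of a region's boundary in the (rho, T) plane,
# closed along the scan edges where the region is censored
region_area <- function(region, scan) {
  pts <- region$points
  if (region$empty || nrow(pts) < 2) {
    return(list(area = 0, censored = TRUE))
  }
  grid <- scan_points(scan)
  T_lo <- min(grid$T)
  censored <- FALSE
  if (region$kind == "density" || grepl("^orientational", region$kind)) {
    # locus curve (one point per density or per isotherm): the anomalous
    # region lies below the curve; close along the scan's lower T edge
    if (region$kind == "density") {
      ord <- pts[order(pts$rho), ]
      poly_x <- c(ord$rho, rev(ord$rho))
      poly_y <- c(ord$T, rep(T_lo, nrow(ord)))
    } else {
      ord <- pts[order(pts$T), ]
      poly_x <- c(ord$rho, rev(ord$rho))
      poly_y <- c(ord$T, rep(T_lo, nrow(ord)))
    }
    censored <- TRUE  # closure uses the scan edge by construction
  } else {
    lo <- pts[pts$side == "low", ]
    hi <- pts[pts$side == "high", ]
    lo <- lo[order(lo$T), ]
    hi <- hi[order(hi$T, decreasing = TRUE), ]
    if (nrow(lo) < 1 || nrow(hi) < 1) return(list(area = 0, censored = TRUE))
    poly_x <- c(lo$rho, hi$rho)
    poly_y <- c(lo$T, hi$T)
    censored <- min(pts$T) <= T_lo + 1e-12
  }
  n <- length(poly_x)
  if (n < 3) return(list(area = 0, censored = censored))
  j <- c(n, seq_len(n - 1))
  area <- abs(sum(poly_x[j] * poly_y - poly_x * poly_y[j])) / 2
  list(area = area, censored = censored)
}

#' Hierarchy of anomaly regions
#'
#' Orders a set of anomaly regions by their maximum temperature and by their
#' enclosed area in the `(rho, T)` plane and reports the nesting.  When the
#' two orderings disagree, or some regions are empty/degenerate, the nesting
#' is flagged `"partial"` rather than forced into a total order.  Regions
#' whose polygons are closed along the scan edge are flagged censored.
#'
#' @param regions List of `"anomaly_region"` objects (at least 2 non-empty).
#' @param scan The grid scan the regions were derived from.
#' @return List with `table` (one row per region: kind, max temperature,
#'   area, censored flag), `order_by_max_T`, `order_by_area`, `nesting`
#'   (`"total"` or `"partial"`), and a human-readable `statement`.
#' @export
hierarchy_report <- function(regions, scan) {
  keep <- !vapply(regions, function(r) r$empty, logical(1))
  if (sum(keep) < 2) stop("need at least 2 non-empty regions")
  regions <- regions[keep]
  areas <- lapply(regions, region_area, scan = scan)
  tab <- data.frame(
    kind = vapply(regions, function(r) r$kind, character(1)),
    max_temperature = vapply(regions, function(r) r$max_temperature,
                             numeric(1)),
    area = vapply(areas, function(a) a$area, numeric(1)),
    censored = vapply(areas, function(a) a$censored, logical(1)))
  tab <- tab[order(-tab$max_temperature), ]
  rownames(tab) <- NULL
  by_T <- tab$kind
  by_area <- tab$kind[order(-tab$area)]
  nesting <- if (identical(by_T, by_area) && all(tab$area > 0)) "total"
             else "partial"
  statement <- paste0(
    "Anomaly regions ordered by maximum temperature (outermost first): ",
    paste(by_T, collapse = " > "),
    if (nesting == "partial") " [partial: area ordering differs or regions degenerate]"
    else " [consistent with the area ordering]")
  list(table = tab, order_by_max_T = by_T, order_by_area = by_area,
       nesting = nesting, statement = statement)
}
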