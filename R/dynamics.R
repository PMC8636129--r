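# Numerical integration of the replicator flow and vector-field grids.

#' Integrate a replicator trajectory
#'
#' Integrates the replicator system from `init` with the adaptive
#' `lsodar` solver (via \pkg{deSolve}), stopping early once the vector
#' field's sup-norm falls below `conv_tol`.  States are projected onto the
#' closed unit square after integration; the projection magnitude is
#' guarded — exceeding `10 * rtol` signals an integrator problem and raises
#' an error rather than silently distorting the orbit.
#'
#' @param params a [game_params()] object.
#' @param init numeric `(x, y)` starting state in the closed unit square.
#' @param t_max integration horizon (model time units), > 0.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param conv_tol sup-norm threshold on the right-hand side below which
#'   the trajectory counts as converged.
#' @param n_out number of output sampling times on `[0, t_max]`.
#' @return An object of class `"trajectory"`: list with `times`, `states`
#'   (matrix with columns `x`, `y`), `converged` (logical) and `limit`
#'   (final state when converged, else `NULL`).
#' @examples
#' p <- game_params(1, 0.2, 0.1, 1.05, 0.5, 2)
#' tr <- integrate_trajectory(p, c(0.5, 0.5), t_max = 5000)
#' tr$converged
#' @export
integrate_trajectory <- function(params, init, t_max = 1e4,
                                 rtol = 1e-9, atol = 1e-12,
                                 conv_tol = 1e-10, n_out = 400L) {
  p <- as_game_params(params)
  s0 <- check_state(init)
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be > 0", call. = FALSE)

  rhs_fun <- function(t, y, parms) {
    list(c(replicator_fx(p, y[1], y[2]), replicator_gy(p, y[1], y[2])))
  }
  root_fun <- function(t, y, parms) {
    max(abs(replicator_fx(p, y[1], y[2])),
        abs(replicator_gy(p, y[1], y[2]))) - conv_tol
  }

  times <- seq(0, t_max, length.out = max(2L, as.integer(n_out)))
  sol <- deSolve::ode(y = c(x = s0[1], y = s0[2]), times = times,
                      func = rhs_fun, parms = NULL, method = "lsodar",
                      rootfunc = root_fun, rtol = rtol, atol = atol)
  st <- unname(as.matrix(sol[, c("x", "y"), drop = FALSE]))
  colnames(st) <- c("x", "y")

  clip_mag <- max(0, st - 1, -st)
  if (clip_mag > 10 * rtol)
    stop(sprintf(
      "integrator left the unit square by %.3g (> 10 * rtol = %.3g)",
      clip_mag, 10 * rtol), call. = FALSE)
  st <- pmin(pmax(st, 0), 1)

  final <- st[nrow(st), ]
  converged <- max(abs(replicator_rhs(p, final))) < conv_tol
  structure(list(times = unname(sol[, "time"]), states = st,
                 converged = converged,
                 limit = if (converged) final else NULL,
                 params = p, init = s0),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("Replicator trajectory from (%g, %g): %d samples, t in [0, %g]\n",
              x$init[1], x$init[2], n, max(x$times)))
  if (x$converged)
    cat(sprintf("  converged to (%.6g, %.6g)\n", x$limit[1], x$limit[2]))
  else cat("  not converged within the horizon\n")
  invisible(x)
}

#' Long-run limit of the replicator flow from an initial state
#'
#' Integrates the flow and snaps the final state to the nearest rest point
#' (from [enumerate_equilibria()]) within `snap_tol`.  When the trajectory
#' has not converged, or no rest point is within reach of the final state,
#' the diagnostic reports `"undecided"` and no snapping occurs.
#'
#' @inheritParams integrate_trajectory
#' @param snap_tol Euclidean snapping radius around each rest point.
#' @return A list with `state` (the limit, snapped when decided), `decided`
#'   (logical), `equilibrium` (snapped rest point or `NULL`), `t_reached`
#'   (time at which the convergence root fired, `NA` if never) and
#'   `raw_final` (unsnapped final integrated state).
#' @examples
#' p <- game_params(1, 0.2, 0.1, 1.05, 0.5, 2)
#' long_run_state(p, c(0.5, 0.5))$state  # (0, 1)
#' @export
long_run_state <- function(params, init, t_max = 1e4, rtol = 1e-9,
                           atol = 1e-12, conv_tol = 1e-10, snap_tol = 1e-4) {
  p <- as_game_params(params)
  tr <- integrate_trajectory(p, init, t_max = t_max, rtol = rtol,
                             atol = atol, conv_tol = conv_tol)
  final <- tr$states[nrow(tr$states), ]
  eqs <- enumerate_equilibria(p)
  locs <- do.call(rbind, lapply(eqs, function(e) e$location))
  d <- sqrt((locs[, 1] - final[1])^2 + (locs[, 2] - final[2])^2)
  i <- which.min(d)
  decided <- tr$converged && d[i] <= snap_tol
  list(state = if (decided) unname(locs[i, ]) else unname(final),
       decided = decided,
       equilibrium = if (decided) eqs[[i]] else NULL,
       t_reached = if (tr$converged) max(tr$times) else NA_real_,
       raw_final = unname(final))
}

#' Vector-field grid for quiver-style phase diagrams
#'
#' Evaluates the replicator right-hand side on a uniform
#' `resolution x resolution` lattice over the unit square, the raw material
#' for the quiver (vector) diagrams of the game's phase portraits.
#'
#' @param params a [game_params()] object.
#' @param resolution grid points per axis, >= 2.
#' @return A data frame with columns `x`, `y`, `dx`, `dy` and
#'   `resolution^2` rows, classed `"vector_field_grid"`.
#' @examples
#' g <- vector_field_grid(game_params(1, 0.2, 0.1, 1.05, 0.5, 2), 21)
#' subset(g, x == 0.5 & y == 0.5)
#' @export
vector_field_grid <- function(params, resolution = 21L) {
  p <- as_game_params(params)
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 2L)
    stop("resolution must be an integer >= 2", call. = FALSE)
  ax <- seq(0, 1, length.out = resolution)
  grid <- expand.grid(x = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
  grid$dx <- replicator_fx(p, grid$x, grid$y)
  grid$dy <- replicator_gy(p, grid$x, grid$y)
  structure(grid, class = c("vector_field_grid", "data.frame"),
            resolution = resolution)
}

#' Quiver plot of a vector-field grid
#'
#' @param x a [vector_field_grid()] object.
#' @param scale arrow length per unit vector-field magnitude; by default
#'   arrows are normalised to a fixed length so the plot shows direction.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vector_field_grid <- function(x, scale = NULL, ...) {
  res <- attr(x, "resolution")
  len <- 0.6 / (res - 1)
  mag <- sqrt(x$dx^2 + x$dy^2)
  nz <- mag > 0
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "x (share)",
                 ylab = "y (disclose)", asp = 1, ...)
  if (is.null(scale)) {  # direction field: constant-length arrows
    u <- x$dx[nz] / mag[nz] * len
    v <- x$dy[nz] / mag[nz] * len
  } else {
    u <- x$dx[nz] * scale
    v <- x$dy[nz] * scale
  }
  graphics::arrows(x$x[nz], x$y[nz], x$x[nz] + u, x$y[nz] + v,
                   length = 0.03, col = "steelblue4")
  invisible(x)
}

#' Export a trajectory or vector-field grid to CSV
#'
#' Trajectories are written with header `t,x,y`; grids with `x,y,dx,dy`.
#' Floats are rendered with 17 significant digits so round-trips are exact.
#'
#' @param x a `"trajectory"` or `"vector_field_grid"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  if (inherits(x, "trajectory")) {
    df <- data.frame(t = x$times, x = x$states[, 1], y = x$states[, 2])
  } else if (inherits(x, "vector_field_grid")) {
    df <- as.data.frame(x)[, c("x", "y", "dx", "dy")]
  } else stop("unsupported object for export_csv", call. = FALSE)
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
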