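#' Full evolutionary-game analysis of an information-sharing scenario
#'
#' The package's one-stop constructor: validates the parameters, classifies
#' the stability regime, enumerates and classifies all rest points,
#' computes the welfare report (totals, social optimum, alignment with the
#' evolutionary outcome), and — in the bistable regime 2 — the analytic
#' basin probability, optionally backed by a Monte Carlo estimate.
#'
#' @param params a [game_params()] object, a plain named list/vector with
#'   keys `V, L, C, alpha, beta, gamma`, or a path to a YAML/JSON config
#'   file.  Alternatively pass the six scalars directly.
#' @param V,L,C,alpha,beta,gamma scalar parameters, used when `params` is
#'   missing.
#' @param basin_n when non-`NULL` and the set is in regime 2, run
#'   [monte_carlo_basin()] with this many samples.
#' @param seed RNG seed for the Monte Carlo basin estimate.
#' @param overrides optional named list applied on top of `params`
#'   (config-override idiom), e.g. `list(alpha = 1.2)`.
#' @return An object of class `"sharegame"`: list with components `params`,
#'   `regime`, `equilibria`, `welfare`, `optimum`, `alignment`, `basin`
#'   (or `NULL` outside regime 2) and `call`.
#' @examples
#' fit <- sharegame(V = 1, L = 0.2, C = 0.1, alpha = 1.05, beta = 0.5,
#'                  gamma = 2)
#' summary(fit)
#' @seealso [classify_regime()], [enumerate_equilibria()],
#'   [total_welfare_profiles()], [analytic_basin_probability()]
#' @export
sharegame <- function(params = NULL, V, L, C, alpha, beta, gamma,
                      basin_n = NULL, seed = 1L, overrides = NULL) {
  if (is.null(params)) {
    params <- game_params(V, L, C, alpha, beta, gamma)
  } else if (is.character(params) && length(params) == 1L) {
    params <- read_game_params(params)
  }
  p <- as_game_params(params)
  if (!is.null(overrides)) {
    pl <- unclass(p)
    bad <- setdiff(names(overrides), names(pl))
    if (length(bad))
      stop("unknown override key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    pl[names(overrides)] <- overrides
    p <- do.call(game_params, pl)
  }

  regime <- classify_regime(p)
  equilibria <- enumerate_equilibria(p)
  welfare <- total_welfare_profiles(p)
  optimum <- social_optimum(p)
  alignment <- if (!identical(regime$regime, "degenerate_or_other"))
    alignment_report(p) else NULL
  basin <- NULL
  if (identical(regime$regime, 2L)) {
    basin <- if (is.null(basin_n)) analytic_basin_probability(p)
             else monte_carlo_basin(p, n = basin_n, seed = seed)
  }
  structure(list(params = p, regime = regime, equilibria = equilibria,
                 welfare = welfare, optimum = optimum,
                 alignment = alignment, basin = basin,
                 call = match.call()),
            class = "sharegame")
}

#' @export
print.sharegame <- function(x, ...) {
  cat("Evolutionary game: information sharing vs. disclosure\n")
  print(x$params)
  print(x$regime)
  invisible(x)
}

#' @rdname sharegame
#' @param object,x a `"sharegame"` object.
#' @param ... unused.
#' @export
summary.sharegame <- function(object, ...) {
  structure(list(fit = object), class = "summary.sharegame")
}

#' @export
print.summary.sharegame <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nRest points:\n")
  for (e in f$equilibria) { cat("  "); print(e) }
  cat("\n")
  print(f$welfare)
  if (!is.null(f$optimum$threshold))
    cat(sprintf("Threshold rule: alpha-1 = %.4g vs (L-C)/V = %.4g\n",
                f$optimum$threshold$alpha_minus_1,
                f$optimum$threshold$lc_over_v))
  if (!is.null(f$alignment)) { cat("\n"); print(f$alignment) }
  if (!is.null(f$basin)) { cat("\n"); print(f$basin) }
  invisible(x)
}

#' @export
coef.sharegame <- function(object, ...) {
  unlist(unclass(object$params))
}

#' Predict the long-run outcome from an initial state
#'
#' @param object a [sharegame()] object.
#' @param init numeric `(x, y)` initial state, or a 2-column matrix of
#'   initial states.
#' @param ... passed to [long_run_state()] (e.g. `t_max`).
#' @return For a single state, the [long_run_state()] result; for a matrix,
#'   a data frame with columns `x0`, `y0`, `x`, `y`, `decided`.
#' @export
predict.sharegame <- function(object, init = c(0.5, 0.5), ...) {
  if (is.matrix(init)) {
    rows <- lapply(seq_len(nrow(init)), function(i) {
      lr <- long_run_state(object$params, init[i, ], ...)
      data.frame(x0 = init[i, 1], y0 = init[i, 2],
                 x = lr$state[1], y = lr$state[2], decided = lr$decided)
    })
    return(do.call(rbind, rows))
  }
  long_run_state(object$params, init, ...)
}

#' Simulate long-run outcomes from random initial states
#'
#' Draws `nsim` uniform starting states on the open unit square, runs the
#' replicator flow from each, and tabulates the reached equilibria.
#'
#' @param object a [sharegame()] object.
#' @param nsim number of random starting states.
#' @param seed integer RNG seed.
#' @param ... passed to [long_run_state()].
#' @return A data frame with columns `x0`, `y0`, `x`, `y`, `decided`.
#' @export
simulate.sharegame <- function(object, nsim = 100L, seed = 1L, ...) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  starts <- cbind(stats::runif(nsim), stats::runif(nsim))
  predict(object, init = starts, ...)
}

#' Phase-portrait plot of a fitted game
#'
#' Draws the quiver (direction) field of the replicator system with the
#' rest points overlaid: filled points for stable equilibria, open for
#' unstable, crossed for saddles.
#'
#' @param x a [sharegame()] object.
#' @param resolution grid points per axis for the vector field.
#' @param ... passed to [plot.vector_field_grid()].
#' @export
plot.sharegame <- function(x, resolution = 21L, ...) {
  g <- vector_field_grid(x$params, resolution)
  plot(g, main = sprintf("Replicator flow (regime %s)", x$regime$regime),
       ...)
  for (e in x$equilibria) {
    pch <- switch(e$stability, stable = 19, saddle = 4, 1)
    graphics::points(e$location[1], e$location[2], pch = pch, cex = 1.6,
                     lwd = 2, col = "firebrick")
  }
  invisible(x)
}
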