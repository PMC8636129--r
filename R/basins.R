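# Basin-of-attraction probabilities in the bistable regime and their
# sensitivity to the information-value multiplier alpha.

# internal: require regime 2 with an interior saddle, return its coordinates
require_regime2_saddle <- function(p, what) {
  reg <- classify_regime(p)
  if (!identical(reg$regime, 2L))
    stop(what, " requires a regime-2 parameter set (got regime ",
         reg$regime, ")", call. = FALSE)
  ip <- interior_rest_point(p)
  if (ip$degenerate || !ip$inside)
    stop(what, " requires the interior saddle strictly inside (0,1)^2",
         call. = FALSE)
  ip$point
}

#' Analytic basin-of-attraction probability in the bistable regime
#'
#' In regime 2 the interior saddle `(a, b)` splits the unit square between
#' the two stable profiles (0, 1) (not share, disclose) and (1, 0)
#' (share, not disclose).  Approximating the separatrix by straight lines
#' through the saddle, the probability (area fraction) of converging to
#' (0, 1) is the quadrilateral area
#' \deqn{P_C = \tfrac12 a + \tfrac12 (1-b),}
#' and \eqn{P_B = 1 - P_C} is the probability of converging to (1, 0).
#' A commonly printed simplified fraction,
#' \eqn{1/2 + (L-C-(\alpha-1)V)/((\alpha-1)V-(\gamma-1)C)}, is evaluated
#' alongside; it is not algebraically equal to the area form for general
#' parameters, so both are reported.
#'
#' @param params a [game_params()] object in regime 2.
#' @return An object of class `"basin_estimate"`: list with `p_c_area`,
#'   `p_b` (`= 1 - p_c_area`), `p_c_printed`, `saddle`, and `NULL`
#'   Monte Carlo fields.
#' @examples
#' analytic_basin_probability(game_params(1, 0.2, 0.1, 1.1, 0.5, 2.5))
#' @export
analytic_basin_probability <- function(params) {
  p <- as_game_params(params)
  ab <- require_regime2_saddle(p, "analytic_basin_probability")
  a <- unname(ab[1]); b <- unname(ab[2])
  p_c_area <- 0.5 * a + 0.5 * (1 - b)
  p_c_printed <- 0.5 + (p$L - p$C - (p$alpha - 1) * p$V) /
    ((p$alpha - 1) * p$V - (p$gamma - 1) * p$C)
  structure(list(p_c_area = p_c_area, p_b = 1 - p_c_area,
                 p_c_printed = p_c_printed,
                 saddle = c(a = unname(a), b = unname(b)),
                 p_c_monte_carlo = NULL, n_samples = NULL, seed = NULL,
                 n_undecided = NULL),
            class = "basin_estimate")
}

#' @export
print.basin_estimate <- function(x, ...) {
  cat("Basin of attraction of (0, 1) [not share, disclose]:\n")
  cat(sprintf("  saddle (a, b) = (%.6g, %.6g)\n", x$saddle[1], x$saddle[2]))
  cat(sprintf("  P_C (area form a/2 + (1-b)/2) = %.6g;  P_B = %.6g\n",
              x$p_c_area, x$p_b))
  cat(sprintf("  P_C (printed simplified fraction) = %.6g\n", x$p_c_printed))
  if (!is.null(x$p_c_monte_carlo))
    cat(sprintf("  P_C (Monte Carlo, n = %d, seed = %d) = %.6g  [%d undecided]\n",
                x$n_samples, x$seed, x$p_c_monte_carlo, x$n_undecided))
  invisible(x)
}

#' Monte Carlo basin-of-attraction estimate
#'
#' Draws `n` uniform initial states on the open unit square, runs
#' [long_run_state()] from each, and estimates the basin probability of
#' (0, 1) as the fraction of decided trajectories reaching it.  This is the
#' ground-truth check on the straight-line separatrix approximation of
#' [analytic_basin_probability()].  Undecided trajectories are excluded
#' from the fraction and counted separately; more than 1% of them triggers
#' a warning.
#'
#' @param params a [game_params()] object in regime 2.
#' @param n number of sampled starting states, >= 100.
#' @param seed integer RNG seed; the estimate is deterministic given the
#'   seed.
#' @param t_max integration horizon passed to [long_run_state()].
#' @return A `"basin_estimate"` object with the Monte Carlo fields set
#'   (`p_c_monte_carlo`, `n_samples`, `seed`, `n_undecided`) alongside the
#'   analytic ones.
#' @examples
#' \donttest{
#' monte_carlo_basin(game_params(1, 0.2, 0.1, 1.1, 0.5, 2.5), n = 200, seed = 1)
#' }
#' @export
monte_carlo_basin <- function(params, n = 2000L, seed = 1L, t_max = 1e4) {
  p <- as_game_params(params)
  est <- analytic_basin_probability(p)  # validates regime 2 + saddle
  n <- as.integer(n)
  if (is.na(n) || n < 100L) stop("n must be >= 100", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  starts <- cbind(stats::runif(n), stats::runif(n))

  hits_c <- 0L; hits_b <- 0L; undecided <- 0L
  for (i in seq_len(n)) {
    lr <- long_run_state(p, starts[i, ], t_max = t_max)
    if (!lr$decided) { undecided <- undecided + 1L; next }
    if (max(abs(lr$state - c(0, 1))) == 0) hits_c <- hits_c + 1L
    else if (max(abs(lr$state - c(1, 0))) == 0) hits_b <- hits_b + 1L
    else undecided <- undecided + 1L  # snapped to a non-attractor: count out
  }
  if (undecided > 0.01 * n)
    warning(sprintf("%d of %d trajectories undecided (> 1%%)", undecided, n))
  est$p_c_monte_carlo <- hits_c / (n - undecided)
  est$n_samples <- n
  est$seed <- as.integer(seed)
  est$n_undecided <- undecided
  est
}

#' Sensitivity of the basin probability to the value multiplier alpha
#'
#' Reports three views of \eqn{\partial P_C/\partial \alpha} in regime 2:
#' the closed form \eqn{V(\gamma C - L)/[(\alpha-1)V-(\gamma-1)C]^2} (the
#' exact derivative of the printed simplified fraction), a central finite
#' difference of the printed fraction, and a central finite difference of
#' the area form.  For each, the sign is reported together with whether the
#' qualitative rule "positive iff \eqn{\gamma C > L}" holds.
#'
#' @param params a [game_params()] object in regime 2, and still regime 2
#'   at `alpha - delta` and `alpha + delta`.
#' @param delta finite-difference half-width on alpha.
#' @return A list of class `"basin_sensitivity"` with components `closed_form`,
#'   `fd_printed`, `fd_area`, each a list with `value`, `sign`, and
#'   `sign_rule_holds`, plus `gammaC_minus_L`.
#' @examples
#' basin_sensitivity(game_params(1, 0.2, 0.1, 1.1, 0.5, 2.5))
#' @export
basin_sensitivity <- function(params, delta = 1e-4) {
  p <- as_game_params(params)
  require_regime2_saddle(p, "basin_sensitivity")
  shift <- function(da) {
    q <- p; q$alpha <- p$alpha + da
    q <- do.call(game_params, unclass(q))
    if (!identical(classify_regime(q)$regime, 2L))
      stop("parameter set leaves regime 2 within the finite-difference ",
           "stencil; use a smaller delta", call. = FALSE)
    analytic_basin_probability(q)
  }
  lo <- shift(-delta); hi <- shift(delta)
  closed <- p$V * (p$gamma * p$C - p$L) /
    ((p$alpha - 1) * p$V - (p$gamma - 1) * p$C)^2
  fd_printed <- (hi$p_c_printed - lo$p_c_printed) / (2 * delta)
  fd_area <- (hi$p_c_area - lo$p_c_area) / (2 * delta)
  rule_pos <- p$gamma * p$C > p$L  # the qualitative sign rule's premise
  view <- function(v) list(value = v, sign = sign(v),
                           sign_rule_holds = (v > 0) == rule_pos)
  structure(list(closed_form = view(closed),
                 fd_printed = view(fd_printed),
                 fd_area = view(fd_area),
                 gammaC_minus_L = p$gamma * p$C - p$L,
                 delta = delta),
            class = "basin_sensitivity")
}

#' @export
print.basin_sensitivity <- function(x, ...) {
  cat("Sensitivity of P_C to alpha (regime 2):\n")
  cat(sprintf("  closed form V(gC-L)/[(a-1)V-(g-1)C]^2 = %.6g\n",
              x$closed_form$value))
  cat(sprintf("  finite difference, printed fraction   = %.6g\n",
              x$fd_printed$value))
  cat(sprintf("  finite difference, area form          = %.6g\n",
              x$fd_area$value))
  cat(sprintf("  gamma*C - L = %.6g; sign rule (dP_C/dalpha > 0 iff gamma*C > L) holds: closed %s, printed %s, area %s\n",
              x$gammaC_minus_L, x$closed_form$sign_rule_holds,
              x$fd_printed$sign_rule_holds, x$fd_area$sign_rule_holds))
  invisible(x)
}
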