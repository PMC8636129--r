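# Rest points, Jacobian, local stability, and regime classification.

.eps_hyperbolic <- 1e-9   # |Re(lambda)| below this => non-hyperbolic
.eps_boundary   <- 1e-12  # regime inequalities within this of 0 => degenerate

#' Interior rest point of the replicator system
#'
#' Setting the bracketed factors of the replicator system to zero gives the
#' interior candidate
#' \deqn{a = (L-C) / ((\gamma-1)C - (\alpha-1)L), \qquad
#'       b = (\alpha-1)V / ((\gamma-1)C - (\alpha-1)L).}
#'
#' With `printed = TRUE` the formulas are evaluated with the denominator of
#' opposite sign, `(\alpha-1)L - (\gamma-1)C`, as some treatments print
#' them; under regime-2 parameter sets those printed forms land outside the
#' unit square while the flow's saddle is at the derived `(a, b)`.  The
#' derived form is the default and the one used throughout the package.
#'
#' @param params a [game_params()] object.
#' @param printed logical; evaluate the printed-variant formulas instead of
#'   the derived ones.
#' @return A list with `point` (numeric `(a, b)`, or `NULL` when the
#'   denominator degenerates), `inside` (logical: both coordinates strictly
#'   within (0,1)), and `degenerate` (logical).
#' @examples
#' interior_rest_point(game_params(1, 0.2, 0.1, 1.1, 0.5, 2.5))$point # 10/13
#' @export
interior_rest_point <- function(params, printed = FALSE) {
  p <- as_game_params(params)
  den <- (p$gamma - 1) * p$C - (p$alpha - 1) * p$L
  if (printed) den <- -den
  if (abs(den) < .Machine$double.eps * 100 * max(1, abs(p$C), abs(p$L)))
    return(list(point = NULL, inside = FALSE, degenerate = TRUE))
  a <- (p$L - p$C) / den
  b <- (p$alpha - 1) * p$V / den
  list(point = c(x = a, y = b),
       inside = (a > 0 && a < 1 && b > 0 && b < 1),
       degenerate = FALSE)
}

#' Jacobian of the replicator system at a state
#'
#' Closed-form entries of the Jacobian (coefficient) matrix of the
#' two-dimensional replicator system:
#' \deqn{c_{11} = (1-2x)\{[(\alpha-1)\beta L-(\gamma-1)\beta C]y+(\alpha-1)\beta V\}}
#' \deqn{c_{12} = x(1-x)[(\alpha-1)\beta L-(\gamma-1)\beta C]}
#' \deqn{c_{21} = y(1-y)(1-\beta)[(\alpha-1)L-(\gamma-1)C]}
#' \deqn{c_{22} = (1-2y)\{x(1-\beta)[(\alpha-1)L-(\gamma-1)C]+(1-\beta)(L-C)\}}
#'
#' @param params a [game_params()] object.
#' @param state numeric `(x, y)` in the closed unit square.
#' @return A 2x2 numeric matrix.
#' @examples
#' jacobian_at(game_params(1, 0.2, 0.1, 1.05, 0.5, 2), c(0, 1))
#' @export
jacobian_at <- function(params, state) {
  p <- as_game_params(params)
  s <- check_state(state)
  x <- s[1]; y <- s[2]
  kx <- (p$alpha - 1) * p$beta * p$L - (p$gamma - 1) * p$beta * p$C
  ky <- (1 - p$beta) * ((p$alpha - 1) * p$L - (p$gamma - 1) * p$C)
  c11 <- (1 - 2 * x) * (kx * y + (p$alpha - 1) * p$beta * p$V)
  c12 <- x * (1 - x) * kx
  c21 <- y * (1 - y) * ky
  c22 <- (1 - 2 * y) * (x * ky + (1 - p$beta) * (p$L - p$C))
  matrix(c(c11, c21, c12, c22), nrow = 2,
         dimnames = list(c("dx", "dy"), c("x", "y")))
}

#' Classify the local stability of a rest point
#'
#' Evaluates the Jacobian at `state`, solves the characteristic equation
#' `lambda^2 - (c11+c22) lambda + (c11 c22 - c12 c21) = 0`, and classifies:
#' `stable` when both eigenvalue real parts are negative (equivalently, at
#' hyperbolic points, trace < 0 and determinant > 0), `unstable` when both
#' are positive, `saddle` for real eigenvalues of opposite sign, and
#' `non_hyperbolic` when any real part is within `eps_hyperbolic` of zero.
#'
#' @param params a [game_params()] object.
#' @param state a rest point of the replicator system: `replicator_rhs` at
#'   `state` must vanish to within `rest_tol`.
#' @param rest_tol tolerance for the rest-point precondition.
#' @param eps_hyperbolic threshold below which an eigenvalue real part
#'   counts as zero.
#' @return An object of class `"equilibrium_report"`: list with `location`,
#'   `kind` (`"corner"` or `"interior"`), `jacobian` (2x2 matrix),
#'   `eigenvalues` (length-2, possibly complex), and `stability`.
#' @examples
#' classify_equilibrium(game_params(1, 0.2, 0.1, 1.05, 0.5, 2), c(0, 1))
#' @export
classify_equilibrium <- function(params, state, rest_tol = 1e-8,
                                 eps_hyperbolic = .eps_hyperbolic) {
  p <- as_game_params(params)
  s <- check_state(state)
  rhs <- replicator_rhs(p, s)
  if (max(abs(rhs)) > rest_tol)
    stop(sprintf(
      "state (%g, %g) is not a rest point: |rhs| = %.3g exceeds %.3g",
      s[1], s[2], max(abs(rhs)), rest_tol), call. = FALSE)
  J <- jacobian_at(p, s)
  lam <- eigen(J, only.values = TRUE)$values
  re <- Re(lam)
  stability <-
    if (any(abs(re) <= eps_hyperbolic)) "non_hyperbolic"
    else if (all(re < 0)) "stable"
    else if (all(re > 0)) "unstable"
    else if (all(Im(lam) == 0)) "saddle"
    else "unstable"  # complex pair, positive real part on one: cannot occur
                     # for real 2x2 (complex pairs share the real part)
  kind <- if (all(s %in% c(0, 1))) "corner" else "interior"
  structure(list(location = c(x = s[1], y = s[2]), kind = kind,
                 jacobian = J, eigenvalues = lam, stability = stability),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  lam <- x$eigenvalues
  fmt_lam <- if (all(Im(lam) == 0)) sprintf("%.6g", Re(lam))
             else sprintf("%.6g%+.6gi", Re(lam), Im(lam))
  cat(sprintf("%s rest point (%g, %g): %s  [lambda = %s]\n",
              x$kind, x$location[1], x$location[2], x$stability,
              paste(fmt_lam, collapse = ", ")))
  invisible(x)
}

#' Enumerate the rest points of the game
#'
#' The four corners of the unit square are always rest points; the interior
#' candidate `(a, b)` from [interior_rest_point()] is included when both
#' coordinates lie strictly inside (0, 1).  Each rest point is returned as a
#' classified [classify_equilibrium()] report.
#'
#' @param params a [game_params()] object.
#' @return A list of `equilibrium_report` objects (4 or 5 elements), with
#'   attribute `"interior_degenerate"` set to `TRUE` when the interior
#'   candidate's denominator degenerates (`(gamma-1)C == (alpha-1)L`).
#' @examples
#' length(enumerate_equilibria(game_params(1, 0.2, 0.1, 1.1, 0.5, 2.5))) # 5
#' @export
enumerate_equilibria <- function(params) {
  p <- as_game_params(params)
  corners <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  reports <- lapply(corners, function(s) classify_equilibrium(p, s))
  ip <- interior_rest_point(p)
  if (!ip$degenerate && ip$inside)
    reports <- c(reports, list(classify_equilibrium(p, ip$point)))
  attr(reports, "interior_degenerate") <- ip$degenerate
  reports
}

#' Classify a parameter set into a stability regime
#'
#' The three regimes are defined by strict inequalities among
#' `(alpha-1)(V+L)` vs `(gamma-1)C`, `L` vs `C`, and `alpha*L` vs `gamma*C`
#' (the users' share `beta` cancels from the first condition and plays no
#' role):
#'
#' * regime 1: `(alpha-1)(V+L) < (gamma-1)C`, `L > C`, `alpha*L > gamma*C`
#'   — the unique stable profile is (not share, disclose) = (0, 1);
#' * regime 2: `(alpha-1)(V+L) < (gamma-1)C`, `L > C`, `alpha*L < gamma*C`
#'   — two stable profiles, (0, 1) and (1, 0), separated by an interior
#'   saddle;
#' * regime 3: `(alpha-1)(V+L) > (gamma-1)C`, `alpha*L > gamma*C` — the
#'   unique stable profile is (share, disclose) = (1, 1).
#'
#' Parameter sets on (within `eps_boundary` of) a regime boundary, or
#' satisfying none of the three, are labelled `"degenerate_or_other"`.
#'
#' @param params a [game_params()] object.
#' @param eps_boundary equality tolerance for the regime inequalities.
#' @return An object of class `"regime_classification"`: list with `regime`
#'   (`1`, `2`, `3` or `"degenerate_or_other"`), `conditions` (signs of the
#'   three defining differences), and `stable_set` (list of corner
#'   coordinates predicted stable).
#' @examples
#' classify_regime(game_params(1, 0.2, 0.1, 1.05, 0.5, 2))$regime  # 1
#' @export
classify_regime <- function(params, eps_boundary = .eps_boundary) {
  p <- as_game_params(params)
  d_growth <- (p$alpha - 1) * (p$V + p$L) - (p$gamma - 1) * p$C
  d_lc     <- p$L - p$C
  d_algc   <- p$alpha * p$L - p$gamma * p$C
  sgn <- function(d) if (abs(d) <= eps_boundary) 0L else sign(d)
  s <- c(growth_vs_cost = sgn(d_growth), L_vs_C = sgn(d_lc),
         alphaL_vs_gammaC = sgn(d_algc))
  regime <- "degenerate_or_other"
  stable_set <- list()
  if (s[1] == -1 && s[2] == 1 && s[3] == 1) {
    regime <- 1L; stable_set <- list(c(0, 1))
  } else if (s[1] == -1 && s[2] == 1 && s[3] == -1) {
    regime <- 2L; stable_set <- list(c(0, 1), c(1, 0))
  } else if (s[1] == 1 && s[3] == 1) {
    regime <- 3L; stable_set <- list(c(1, 1))
  }
  structure(list(regime = regime,
                 conditions = list(
                   `(alpha-1)(V+L) - (gamma-1)C` = unname(s[1]),
                   `L - C` = unname(s[2]),
                   `alpha*L - gamma*C` = unname(s[3])),
                 stable_set = stable_set),
            class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat("Stability regime:", x$regime, "\n")
  if (length(x$stable_set)) {
    lab <- vapply(x$stable_set,
                  function(s) sprintf("(%g, %g)", s[1], s[2]), "")
    cat("  stable strategy profile(s):", paste(lab, collapse = ", "), "\n")
  } else {
    cat("  no regime-predicted stable corners (degenerate/other)\n")
  }
  invisible(x)
}
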