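#' Payoff bimatrix of the user/government game
#'
#' Builds the 2x2 bimatrix of (user, government) payoffs for the four pure
#' strategy profiles.  The total social value realised in each profile is
#' split `beta` to the user and `1 - beta` to the government:
#'
#' * (share, disclose): user `alpha*beta*(V+L) - gamma*beta*C`, government
#'   `(1-beta)*alpha*(V+L) - (1-beta)*gamma*C`
#' * (share, not disclose): user `alpha*beta*V`, government `alpha*(1-beta)*V`
#' * (not share, disclose): user `beta*(V+L) - beta*C`, government
#'   `(1-beta)*(V+L) - (1-beta)*C`
#' * (not share, not disclose): user `beta*V`, government `(1-beta)*V`
#'
#' @param params a [game_params()] object.
#' @return An object of class `"payoff_matrix"`: a list with a `cells`
#'   component, a 4-row data frame with columns `share` (`"share"` or
#'   `"not_share"`), `disclose` (`"disclose"` or `"not_disclose"`),
#'   `user` and `government` payoffs.
#' @examples
#' payoff_matrix(game_params(1, 0.2, 0.1, 1.05, 0.5, 2))
#' @export
payoff_matrix <- function(params) {
  p <- as_game_params(params)
  b <- p$beta
  cells <- data.frame(
    share    = c("share", "share", "not_share", "not_share"),
    disclose = c("disclose", "not_disclose", "disclose", "not_disclose"),
    user = c(
      p$alpha * b * (p$V + p$L) - p$gamma * b * p$C,
      p$alpha * b * p$V,
      b * (p$V + p$L) - b * p$C,
      b * p$V),
    government = c(
      (1 - b) * p$alpha * (p$V + p$L) - (1 - b) * p$gamma * p$C,
      p$alpha * (1 - b) * p$V,
      (1 - b) * (p$V + p$L) - (1 - b) * p$C,
      (1 - b) * p$V),
    stringsAsFactors = FALSE)
  structure(list(cells = cells, params = p), class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("Payoff bimatrix (user, government):\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

# internal: fetch one (user, government) payoff pair
payoff_cell <- function(pm, share, disclose) {
  i <- which(pm$cells$share == share & pm$cells$disclose == disclose)
  c(user = pm$cells$user[i], government = pm$cells$government[i])
}

#' Expected payoffs at a mixed-strategy state
#'
#' Given the state `(x, y)` — `x` the probability a user shares, `y` the
#' probability the government discloses — computes the user's expected
#' payoff from sharing (`user_share`), from not sharing (`user_not_share`)
#' and the population average `user_average = x*user_share +
#' (1-x)*user_not_share`; analogously for the government over disclosure.
#'
#' @param params a [game_params()] object.
#' @param state numeric `(x, y)` in the closed unit square.
#' @return A named list with components `user_share`, `user_not_share`,
#'   `user_average`, `gov_disclose`, `gov_not_disclose`, `gov_average`.
#' @examples
#' p <- game_params(1, 0.2, 0.1, 1.05, 0.5, 2)
#' expected_payoffs(p, c(0.5, 0.5))
#' @export
expected_payoffs <- function(params, state) {
  p <- as_game_params(params)
  s <- check_state(state)
  x <- s[1]; y <- s[2]
  pm <- payoff_matrix(p)$cells
  u <- function(share, disclose)
    pm$user[pm$share == share & pm$disclose == disclose]
  g <- function(share, disclose)
    pm$government[pm$share == share & pm$disclose == disclose]

  user_share     <- y * u("share", "disclose")     + (1 - y) * u("share", "not_disclose")
  user_not_share <- y * u("not_share", "disclose") + (1 - y) * u("not_share", "not_disclose")
  gov_disclose     <- x * g("share", "disclose")     + (1 - x) * g("not_share", "disclose")
  gov_not_disclose <- x * g("share", "not_disclose") + (1 - x) * g("not_share", "not_disclose")

  list(user_share = user_share,
       user_not_share = user_not_share,
       user_average = x * user_share + (1 - x) * user_not_share,
       gov_disclose = gov_disclose,
       gov_not_disclose = gov_not_disclose,
       gov_average = y * gov_disclose + (1 - y) * gov_not_disclose)
}

#' Replicator right-hand side
#'
#' The replicator system for the game, in closed form:
#' \deqn{dx/dt = x(1-x)\{[(\alpha-1)\beta L-(\gamma-1)\beta C]\,y+(\alpha-1)\beta V\}}
#' \deqn{dy/dt = y(1-y)\{x(1-\beta)[(\alpha-1)L-(\gamma-1)C]+(1-\beta)(L-C)\}}
#'
#' The same vector field equals the generic replicator form
#' `x * (user_share - user_average)` and `y * (gov_disclose - gov_average)`
#' built from [expected_payoffs()]; the two derivations are kept consistent
#' by tests.
#'
#' @param params a [game_params()] object.
#' @param state numeric `(x, y)` in the closed unit square, or a 2-column
#'   matrix of states (one row per state).
#' @return For a single state, a named numeric vector `c(dx, dy)`; for a
#'   matrix of states, a 2-column matrix with columns `dx`, `dy`.
#' @examples
#' p <- game_params(1, 0.2, 0.1, 1.05, 0.5, 2)
#' replicator_rhs(p, c(0.5, 0.5))  # c(0.000625, 0.006875)
#' @export
replicator_rhs <- function(params, state) {
  p <- as_game_params(params)
  if (is.matrix(state)) {
    if (ncol(state) != 2L) stop("state matrix must have 2 columns", call. = FALSE)
    apply(state, 1L, check_state)  # validates; result discarded
    x <- state[, 1]; y <- state[, 2]
    out <- cbind(dx = replicator_fx(p, x, y), dy = replicator_gy(p, x, y))
    return(out)
  }
  s <- check_state(state)
  c(dx = replicator_fx(p, s[1], s[2]), dy = replicator_gy(p, s[1], s[2]))
}

# internal vectorized closed forms (Jacobian and grid code share these)
replicator_fx <- function(p, x, y) {
  x * (1 - x) * (((p$alpha - 1) * p$beta * p$L -
                  (p$gamma - 1) * p$beta * p$C) * y +
                 (p$alpha - 1) * p$beta * p$V)
}

replicator_gy <- function(p, x, y) {
  y * (1 - y) * (x * (1 - p$beta) * ((p$alpha - 1) * p$L -
                                     (p$gamma - 1) * p$C) +
                 (1 - p$beta) * (p$L - p$C))
}
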