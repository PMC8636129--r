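# Social efficiency (welfare) of the four pure strategy profiles and its
# alignment with the evolutionary outcome.

profile_labels <- c(share_disclose = "(share, disclose)",
                    share_not = "(share, not_disclose)",
                    not_disclose = "(not_share, disclose)",
                    not_not = "(not_share, not_disclose)")

# corner of the unit square realising each pure profile
profile_corners <- list(share_disclose = c(1, 1), share_not = c(1, 0),
                        not_disclose = c(0, 1), not_not = c(0, 0))

#' Total social efficiency of the four pure profiles
#'
#' The welfare of a pure profile is the unweighted sum of the user's and
#' the government's payoffs in that cell — the split parameter `beta`
#' cancels, so welfare is beta-free:
#' `alpha*(V+L) - gamma*C`, `alpha*V`, `(V+L) - C`, and `V` for
#' (share, disclose), (share, not disclose), (not share, disclose), and
#' (not share, not disclose) respectively.  The totals are computed both
#' from these closed forms and as cell sums of [payoff_matrix()]; the two
#' routes must agree to 1e-12.
#'
#' @param params a [game_params()] object.
#' @return An object of class `"welfare_report"`: list with `totals`
#'   (named numeric: `share_disclose`, `share_not`, `not_disclose`,
#'   `not_not`), `optimum` (name(s) of the argmax profile; length > 1 on
#'   exact ties), and `tie` (logical).
#' @examples
#' total_welfare_profiles(game_params(1, 0.2, 0.1, 1.05, 0.5, 2))
#' @export
total_welfare_profiles <- function(params) {
  p <- as_game_params(params)
  closed <- c(share_disclose = p$alpha * (p$V + p$L) - p$gamma * p$C,
              share_not = p$alpha * p$V,
              not_disclose = (p$V + p$L) - p$C,
              not_not = p$V)
  pm <- payoff_matrix(p)
  sums <- c(share_disclose = sum(payoff_cell(pm, "share", "disclose")),
            share_not = sum(payoff_cell(pm, "share", "not_disclose")),
            not_disclose = sum(payoff_cell(pm, "not_share", "disclose")),
            not_not = sum(payoff_cell(pm, "not_share", "not_disclose")))
  if (max(abs(closed - sums)) > 1e-12)
    stop("internal inconsistency: closed-form welfare totals disagree with ",
         "payoff-matrix cell sums", call. = FALSE)
  mx <- max(closed)
  opt <- names(closed)[closed >= mx - 1e-12]
  structure(list(totals = closed, optimum = opt, tie = length(opt) > 1L),
            class = "welfare_report")
}

#' @export
print.welfare_report <- function(x, ...) {
  cat("Total social efficiency of the pure profiles (beta-free):\n")
  for (nm in names(x$totals))
    cat(sprintf("  %-28s %.6g%s\n", profile_labels[[nm]], x$totals[[nm]],
                if (nm %in% x$optimum) "  <- optimum" else ""))
  if (x$tie) cat("  note: exact tie among the marked profiles\n")
  invisible(x)
}

#' Socially optimal pure profile
#'
#' Returns the welfare-maximising profile.  In regimes 1 and 2 the contest
#' is between (not share, disclose) with welfare `(V+L) - C` and
#' (share, not disclose) with welfare `alpha*V`; the threshold rule
#' `(alpha - 1)` vs `(L - C)/V` decides it, and its verdict is
#' cross-checked against the direct argmax.  Exact ties are reported as
#' ties, never broken silently.
#'
#' @param params a [game_params()] object.
#' @return A list of class `"social_optimum"`: `optimum` (profile name(s)),
#'   `tie`, `totals`, `regime`, and in regimes 1-2 a `threshold` list with
#'   `alpha_minus_1`, `lc_over_v`, `favours` and `agrees_with_argmax`.
#' @examples
#' social_optimum(game_params(1, 0.2, 0.1, 1.05, 0.5, 2))
#' @export
social_optimum <- function(params) {
  p <- as_game_params(params)
  wf <- total_welfare_profiles(p)
  reg <- classify_regime(p)
  threshold <- NULL
  if (identical(reg$regime, 1L) || identical(reg$regime, 2L)) {
    a1 <- p$alpha - 1
    lcv <- (p$L - p$C) / p$V
    favours <- if (a1 < lcv) "not_disclose"
               else if (a1 > lcv) "share_not"
               else "tie"
    # the rule only ranks the two contenders; check it against their totals
    contender_rank <- if (wf$totals["not_disclose"] > wf$totals["share_not"])
      "not_disclose" else if (wf$totals["not_disclose"] < wf$totals["share_not"])
      "share_not" else "tie"
    threshold <- list(alpha_minus_1 = a1, lc_over_v = lcv, favours = favours,
                      agrees_with_argmax = identical(favours, contender_rank))
  }
  structure(list(optimum = wf$optimum, tie = wf$tie, totals = wf$totals,
                 regime = reg$regime, threshold = threshold),
            class = "social_optimum")
}

#' @export
print.social_optimum <- function(x, ...) {
  cat("Social optimum:",
      paste(profile_labels[x$optimum], collapse = " / "),
      if (x$tie) "(exact tie)" else "", "\n")
  if (!is.null(x$threshold))
    cat(sprintf("  threshold rule: alpha-1 = %.6g vs (L-C)/V = %.6g -> favours %s (argmax agreement: %s)\n",
                x$threshold$alpha_minus_1, x$threshold$lc_over_v,
                x$threshold$favours, x$threshold$agrees_with_argmax))
  invisible(x)
}

#' Alignment of the evolutionary outcome with the social optimum
#'
#' Compares the stable strategy profiles predicted by the parameter regime
#' (individual rationality under replicator dynamics) with the
#' welfare-maximising profile (collective rationality).  `aligned` is
#' `TRUE` iff the optimum's corner belongs to the regime's stable set.  In
#' regime 2, both stable corners are reported individually — only one of
#' them is the optimum, so which long-run outcome is socially optimal
#' depends on the basin the game starts in; the corresponding basin
#' probability from [analytic_basin_probability()] is attached.
#'
#' @param params a [game_params()] object classifiable into regime 1, 2
#'   or 3; degenerate parameter sets yield an error.
#' @return A list of class `"alignment_report"`: `regime`, `optimum`,
#'   `stable_set`, `aligned`, and for regime 2 `per_corner` (data frame
#'   with columns `x`, `y`, `profile`, `is_optimum`, `basin_probability`).
#' @examples
#' alignment_report(game_params(1, 0.2, 0.1, 1.05, 0.5, 2))
#' @export
alignment_report <- function(params) {
  p <- as_game_params(params)
  reg <- classify_regime(p)
  if (identical(reg$regime, "degenerate_or_other"))
    stop("alignment is only defined for regimes 1-3; parameter set is ",
         "degenerate or outside the three regimes", call. = FALSE)
  opt <- social_optimum(p)
  opt_corners <- profile_corners[opt$optimum]
  in_stable <- function(corner)
    any(vapply(reg$stable_set,
               function(s) all(s == corner), logical(1)))
  aligned <- any(vapply(opt_corners, in_stable, logical(1)))
  per_corner <- NULL
  if (identical(reg$regime, 2L)) {
    basin <- analytic_basin_probability(p)
    per_corner <- do.call(rbind, lapply(reg$stable_set, function(s) {
      prof <- names(Filter(function(pc) all(pc == s), profile_corners))
      data.frame(x = s[1], y = s[2], profile = prof,
                 is_optimum = prof %in% opt$optimum,
                 basin_probability = if (all(s == c(0, 1))) basin$p_c_area
                                     else basin$p_b,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(regime = reg$regime, optimum = opt$optimum,
                 stable_set = reg$stable_set, aligned = aligned,
                 per_corner = per_corner),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("Regime %s: evolutionary outcome %s the social optimum %s\n",
              x$regime, if (x$aligned) "can reach" else "misses",
              paste(profile_labels[x$optimum], collapse = " / ")))
  if (!is.null(x$per_corner)) {
    cat("  per stable corner (regime 2):\n")
    for (i in seq_len(nrow(x$per_corner)))
      cat(sprintf("    (%g, %g) %s: %s, basin probability %.4g\n",
                  x$per_corner$x[i], x$per_corner$y[i],
                  profile_labels[x$per_corner$profile[i]],
                  if (x$per_corner$is_optimum[i]) "socially optimal"
                  else "not optimal",
                  x$per_corner$basin_probability[i]))
  }
  invisible(x)
}
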