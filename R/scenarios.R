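# Scenario fixtures and regime-constrained random parameter sampling.

#' The three benchmark parameter scenarios
#'
#' One fixture per stability regime, each a full parameter assignment:
#'
#' * `S1` (regime 1): `V=1, L=0.2, C=0.1, alpha=1.05, beta=0.5, gamma=2`
#'   — unique stable profile (0, 1);
#' * `S2` (regime 2): `V=1, L=0.2, C=0.1, alpha=1.1, beta=0.5, gamma=2.5`
#'   — bistable, stable profiles (0, 1) and (1, 0) with an interior saddle;
#' * `S3` (regime 3): `V=1, L=0.2, C=0.1, alpha=1.1, beta=0.5, gamma=1.1`
#'   — unique stable profile (1, 1).
#'
#' @return A named list of three fixtures, each a list with `name`,
#'   `params` ([game_params()]), `expected_regime` and
#'   `expected_stable_set`.
#' @examples
#' printed_scenarios()$S1$params
#' @export
printed_scenarios <- function() {
  fx <- function(name, alpha, gamma, regime, stable_set)
    list(name = name,
         params = game_params(V = 1, L = 0.2, C = 0.1, alpha = alpha,
                              beta = 0.5, gamma = gamma),
         expected_regime = regime,
         expected_stable_set = stable_set)
  list(S1 = fx("S1", 1.05, 2, 1L, list(c(0, 1))),
       S2 = fx("S2", 1.10, 2.5, 2L, list(c(0, 1), c(1, 0))),
       S3 = fx("S3", 1.10, 1.1, 3L, list(c(1, 1))))
}

#' Default parameter bounds for regime-constrained sampling
#'
#' Ranges bracketing the benchmark scenarios with healthy rejection-sampling
#' acceptance rates in every regime.
#'
#' @return A named list of length-2 numeric ranges for `V`, `L`, `C`,
#'   `alpha`, `beta`, `gamma`.
#' @export
default_parameter_bounds <- function() {
  list(V = c(0.5, 2), L = c(0.05, 0.5), C = c(0.02, 0.4),
       alpha = c(1.01, 1.5), beta = c(0.2, 0.8), gamma = c(1.01, 3))
}

#' Sample random parameter sets constrained to a stability regime
#'
#' Uniform rejection sampling: draws each parameter independently and
#' uniformly within `bounds` and keeps draws whose [classify_regime()]
#' label equals `regime`.  Deterministic given `seed`.  If fewer than one
#' draw in 10,000 is accepted the bounds are deemed infeasible for the
#' requested regime and an error advises widening them.
#'
#' @param regime target regime, 1, 2 or 3.
#' @param n number of parameter sets to return, >= 1.
#' @param seed integer RNG seed.
#' @param bounds named list of length-2 ranges as in
#'   [default_parameter_bounds()]; ranges must respect the parameter
#'   invariants (`alpha`, `gamma` above 1, `beta` inside (0,1), positives).
#' @return A list of `n` [game_params()] objects with attribute
#'   `"acceptance_rate"`.
#' @examples
#' sets <- sample_regime_parameters(2, n = 5, seed = 42)
#' attr(sets, "acceptance_rate")
#' @export
sample_regime_parameters <- function(regime, n, seed = 1L,
                                     bounds = default_parameter_bounds()) {
  if (!regime %in% 1:3) stop("regime must be 1, 2 or 3", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  keys <- c("V", "L", "C", "alpha", "beta", "gamma")
  if (!all(keys %in% names(bounds)))
    stop("bounds must name all of ", paste(keys, collapse = ", "),
         call. = FALSE)
  lo <- vapply(bounds[keys], `[`, numeric(1), 1L)
  hi <- vapply(bounds[keys], `[`, numeric(1), 2L)
  if (any(hi <= lo)) stop("each bound range must have lower < upper",
                          call. = FALSE)
  if (lo["alpha"] <= 1 || lo["gamma"] <= 1 ||
      lo["beta"] <= 0 || hi["beta"] >= 1 ||
      any(lo[c("V", "L", "C")] <= 0))
    stop("bounds violate the parameter invariants (alpha, gamma > 1; ",
         "0 < beta < 1; V, L, C > 0)", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  accepted <- vector("list", n)
  n_acc <- 0L; n_try <- 0L
  max_try <- max(1e5, n / 1e-4)
  while (n_acc < n) {
    chunk <- max(2L, min(1000L, as.integer((n - n_acc) * 50)))
    draws <- matrix(stats::runif(chunk * length(keys)), nrow = chunk,
                    dimnames = list(NULL, keys))
    for (j in seq_along(keys))
      draws[, j] <- lo[j] + draws[, j] * (hi[j] - lo[j])
    for (i in seq_len(chunk)) {
      n_try <- n_try + 1L
      p <- do.call(game_params, as.list(draws[i, ]))
      if (identical(classify_regime(p)$regime, as.integer(regime))) {
        n_acc <- n_acc + 1L
        accepted[[n_acc]] <- p
        if (n_acc == n) break
      }
    }
    if (n_try >= max_try && n_acc < n)
      stop(sprintf(paste0(
        "acceptance rate %.2g after %d draws is below 1e-4; the bounds ",
        "appear infeasible for regime %d - widen them"),
        n_acc / n_try, n_try, regime), call. = FALSE)
  }
  attr(accepted, "acceptance_rate") <- n_acc / n_try
  accepted
}

#' Export scenarios or sampled parameter sets to CSV
#'
#' Writes one row per parameter set with columns
#' `name,V,L,C,alpha,beta,gamma`.
#'
#' @param x a list of fixtures (as from [printed_scenarios()]) or of
#'   [game_params()] objects.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
export_scenarios <- function(x, path) {
  rows <- lapply(seq_along(x), function(i) {
    el <- x[[i]]
    if (inherits(el, "game_params"))
      el <- list(name = if (!is.null(names(x))) names(x)[i]
                        else paste0("set", i),
                 params = el)
    data.frame(name = el$name, V = el$params$V, L = el$params$L,
               C = el$params$C, alpha = el$params$alpha,
               beta = el$params$beta, gamma = el$params$gamma,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
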