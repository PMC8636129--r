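#' Game parameters for the information-sharing/disclosure game
#'
#' Constructs and validates the six scalars defining the evolutionary game
#' between online users (share / not share personal pandemic information)
#' and the government (disclose / not disclose collected information).
#'
#' All quantities are dimensionless model units; no currency or scale is
#' imposed.
#'
#' @param V baseline total social value of the information when users do not
#'   share and the government does not disclose; must be > 0.
#' @param L extra social value created by government disclosure; must be > 0.
#' @param C social cost of disclosing self-collected (non-shared)
#'   information; must be > 0.
#' @param alpha information-value multiplier when users share (shared
#'   information is more precise, hence more valuable); must be > 1.
#' @param beta users' share of the total social value, the government
#'   receiving `1 - beta`; must lie strictly in (0, 1).
#' @param gamma cost multiplier when the disclosed information was shared by
#'   users (more precise information leaks more privacy); must be > 1.
#'
#' @return An object of class `"game_params"`: a named list with components
#'   `V`, `L`, `C`, `alpha`, `beta`, `gamma`.
#' @examples
#' p <- game_params(V = 1, L = 0.2, C = 0.1, alpha = 1.05, beta = 0.5, gamma = 2)
#' p
#' @export
game_params <- function(V, L, C, alpha, beta, gamma) {
  for (nm in c("V", "L", "C", "alpha", "beta", "gamma")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop(sprintf("'%s' must be a single finite numeric value", nm),
           call. = FALSE)
  }
  if (V <= 0) stop("'V' must be > 0 (got ", V, ")", call. = FALSE)
  if (L <= 0) stop("'L' must be > 0 (got ", L, ")", call. = FALSE)
  if (C <= 0) stop("'C' must be > 0 (got ", C, ")", call. = FALSE)
  if (alpha <= 1) stop("'alpha' must be > 1 (got ", alpha, ")", call. = FALSE)
  if (gamma <= 1) stop("'gamma' must be > 1 (got ", gamma, ")", call. = FALSE)
  if (beta <= 0 || beta >= 1)
    stop("'beta' must lie strictly in (0, 1) (got ", beta, ")", call. = FALSE)
  structure(list(V = as.numeric(V), L = as.numeric(L), C = as.numeric(C),
                 alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma)),
            class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat("Information sharing/disclosure game parameters\n")
  cat(sprintf("  V = %g, L = %g, C = %g, alpha = %g, beta = %g, gamma = %g\n",
              x$V, x$L, x$C, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' @export
as.list.game_params <- function(x, ...) unclass(x)

# internal: coerce a plain list/vector with the six keys into game_params
as_game_params <- function(x) {
  if (inherits(x, "game_params")) return(x)
  x <- as.list(x)
  keys <- c("V", "L", "C", "alpha", "beta", "gamma")
  missing_keys <- setdiff(keys, names(x))
  if (length(missing_keys))
    stop("missing parameter key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  do.call(game_params, lapply(x[keys], as.numeric))
}

#' Read and write game parameters as flat YAML or JSON configuration
#'
#' The configuration dialect is a flat mapping with the lowercase keys
#' `V, L, C, alpha, beta, gamma` (case-sensitive).  The format is chosen by
#' file extension: `.yml`/`.yaml` for YAML, `.json` for JSON.
#'
#' @param path file to read from or write to.
#' @return `read_game_params()` returns a validated [game_params()] object;
#'   `write_game_params()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_game_params(game_params(1, 0.2, 0.1, 1.05, 0.5, 2), f)
#' read_game_params(f)
#' @export
read_game_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension '", ext,
         "' (use .yaml, .yml or .json)", call. = FALSE))
  as_game_params(cfg)
}

#' @param params a [game_params()] object.
#' @rdname read_game_params
#' @export
write_game_params <- function(params, path) {
  params <- as_game_params(params)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yml = ,
    yaml = yaml::write_yaml(unclass(params), path),
    json = jsonlite::write_json(unclass(params), path,
                                auto_unbox = TRUE, digits = NA),
    stop("unsupported config extension '", ext,
         "' (use .yaml, .yml or .json)", call. = FALSE))
  invisible(path)
}

# internal: validate a mixed-strategy state on the closed unit square
check_state <- function(state) {
  state <- as.numeric(state)
  if (length(state) != 2L || any(!is.finite(state)))
    stop("state must be two finite numbers (x, y)", call. = FALSE)
  if (state[1] < 0 || state[1] > 1 || state[2] < 0 || state[2] > 1)
    stop(sprintf("state (%g, %g) lies outside the unit square [0,1]^2",
                 state[1], state[2]), call. = FALSE)
  state
}
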