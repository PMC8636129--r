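# JSON/CSV serialization of an analysis bundle.

# internal: plain-list view of a sharegame bundle (JSON-ready, stable schema)
bundle_to_list <- function(fit) {
  eq_list <- lapply(fit$equilibria, function(e) {
    J <- e$jacobian
    lam <- e$eigenvalues
    list(location = list(x = unname(e$location[1]), y = unname(e$location[2])),
         kind = e$kind,
         jacobian = list(c11 = J[1, 1], c12 = J[1, 2],
                         c21 = J[2, 1], c22 = J[2, 2]),
         eigenvalues = list(re = Re(lam), im = Im(lam)),
         stability = e$stability)
  })
  basin <- NULL
  if (!is.null(fit$basin)) {
    b <- fit$basin
    basin <- list(p_c_area = b$p_c_area, p_b = b$p_b,
                  p_c_printed = b$p_c_printed,
                  saddle = list(a = unname(b$saddle[1]),
                                b = unname(b$saddle[2])),
                  p_c_monte_carlo = b$p_c_monte_carlo,
                  n_samples = b$n_samples, seed = b$seed,
                  n_undecided = b$n_undecided)
  }
  alignment <- NULL
  if (!is.null(fit$alignment)) {
    a <- fit$alignment
    alignment <- list(aligned = a$aligned, optimum = a$optimum,
                      per_corner = a$per_corner)
  }
  list(params = unclass(fit$params),
       regime = list(regime = fit$regime$regime,
                     conditions = fit$regime$conditions,
                     stable_set = lapply(fit$regime$stable_set,
                                         function(s) list(x = s[1], y = s[2]))),
       equilibria = eq_list,
       welfare = list(totals = as.list(fit$welfare$totals),
                      optimum = fit$welfare$optimum,
                      tie = fit$welfare$tie,
                      threshold = fit$optimum$threshold),
       basin = basin,
       alignment = alignment)
}

# internal: one row per equilibrium, eigenvalues as re/im columns
equilibria_to_df <- function(fit) {
  do.call(rbind, lapply(fit$equilibria, function(e) {
    J <- e$jacobian; lam <- e$eigenvalues
    data.frame(x = unname(e$location[1]), y = unname(e$location[2]),
               c11 = J[1, 1], c12 = J[1, 2], c21 = J[2, 1], c22 = J[2, 2],
               lambda1 = Re(lam[1]), lambda2 = Re(lam[2]),
               lambda1_im = Im(lam[1]), lambda2_im = Im(lam[2]),
               stability = e$stability, stringsAsFactors = FALSE)
  }))
}

#' Export an analysis bundle to files
#'
#' Writes `report.json` (the full bundle), and with `"csv"` among the
#' formats also `equilibria.csv` (one row per rest point with Jacobian
#' entries, eigenvalues and stability class) and `welfare.csv`; with
#' `"png"` a quiver plot `phase.png`; with `field = TRUE` the raw vector
#' field `field.csv`.  Existing files are never overwritten unless
#' `force = TRUE`.  The returned manifest lists every written file with its
#' MD5 checksum; `report.json` carries a `timestamp` field which is
#' excluded from the checksum (the checksum covers the timestamp-free
#' document), so repeated runs with identical inputs yield identical
#' checksums.
#'
#' @param fit a [sharegame()] object.
#' @param out_dir output directory (created if needed).
#' @param formats subset of `c("json", "csv", "png")`.
#' @param field also write the vector-field grid as `field.csv`.
#' @param resolution grid resolution for `field.csv` / `phase.png`.
#' @param force overwrite existing files.
#' @return A data frame manifest with columns `file` and `md5`.
#' @examples
#' fit <- sharegame(V = 1, L = 0.2, C = 0.1, alpha = 1.05, beta = 0.5,
#'                  gamma = 2)
#' dir <- file.path(tempdir(), "s1-report")
#' export_results(fit, dir)
#' @export
export_results <- function(fit, out_dir, formats = c("json", "csv"),
                           field = FALSE, resolution = 21L, force = FALSE) {
  stopifnot(inherits(fit, "sharegame"))
  formats <- match.arg(formats, c("json", "csv", "png"), several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  target <- function(name) {
    path <- file.path(out_dir, name)
    if (file.exists(path) && !force)
      stop("refusing to overwrite existing file ", path,
           " (use force = TRUE)", call. = FALSE)
    path
  }
  written <- character(0)
  md5s <- character(0)

  if ("json" %in% formats) {
    path <- target("report.json")
    doc <- bundle_to_list(fit)
    body <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                             null = "null", pretty = TRUE)
    md5s <- c(md5s, digest_text(body))   # checksum of timestamp-free body
    doc$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    written <- c(written, path)
  }
  if ("csv" %in% formats) {
    path <- target("equilibria.csv")
    utils::write.csv(equilibria_to_df(fit), path, row.names = FALSE)
    written <- c(written, path); md5s <- c(md5s, unname(tools::md5sum(path)))
    path <- target("welfare.csv")
    wdf <- data.frame(profile = names(fit$welfare$totals),
                      total = unname(fit$welfare$totals),
                      is_optimum = names(fit$welfare$totals) %in%
                        fit$welfare$optimum)
    utils::write.csv(wdf, path, row.names = FALSE)
    written <- c(written, path); md5s <- c(md5s, unname(tools::md5sum(path)))
  }
  if (field) {
    path <- target("field.csv")
    export_csv(vector_field_grid(fit$params, resolution), path)
    written <- c(written, path); md5s <- c(md5s, unname(tools::md5sum(path)))
  }
  if ("png" %in% formats) {
    path <- target("phase.png")
    grDevices::png(path, width = 800, height = 800)
    plot(fit, resolution = resolution)
    grDevices::dev.off()
    written <- c(written, path); md5s <- c(md5s, unname(tools::md5sum(path)))
  }
  data.frame(file = written, md5 = md5s, stringsAsFactors = FALSE)
}

# internal: md5 of a character scalar without touching disk twice
digest_text <- function(txt) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}
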