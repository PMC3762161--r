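#' Read and write parameter configurations
#'
#' Parameter sets round-trip through a flat key--value YAML file whose keys
#' are exactly the [model_params()] field names, plus optional top-level
#' `epsilon`, `profile_m` (bump exponent) and `K`. A `presets` section may
#' map names to full parameter sets.
#'
#' @param path YAML file path.
#' @return `read_config` returns a list with `params`
#'   (a [model_params()]), and when present `epsilon`, `theta`, `K`.
#' @name config_io
NULL

#' @rdname config_io
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pfields <- names(formals(model_params))
  pargs <- raw[intersect(names(raw), pfields)]
  out <- list(params = do.call(model_params, pargs))
  if (!is.null(raw$epsilon)) out$epsilon <- raw$epsilon
  if (!is.null(raw$profile_m)) out$theta <- bump_profile(raw$profile_m)
  if (!is.null(raw$K)) out$K <- raw$K
  if (!is.null(raw$presets)) out$presets <- raw$presets
  out
}

#' @rdname config_io
#' @param params A [model_params()] object.
#' @param epsilon,profile_m,K Optional extras stored alongside.
#' @export
write_config <- function(params, path, epsilon = NULL, profile_m = NULL,
                         K = NULL) {
  x <- unclass(params)
  if (!is.null(epsilon)) x$epsilon <- epsilon
  if (!is.null(profile_m)) x$profile_m <- profile_m
  if (!is.null(K)) x$K <- K
  yaml::write_yaml(x, path)
  invisible(path)
}

# long-format CSV with stable 12-significant-digit formatting
write_fields_csv <- function(tab, file) {
  out <- tab
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    trimws(formatC(x, digits = 12, format = "g")))
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export a field solution to CSV with a JSON metadata sidecar
#'
#' Writes the `(y, t, v, c, f, eta)` table to `<stem>.csv` (12 significant
#' digits) and a `<stem>.json` sidecar recording provenance, parameters,
#' truncation order and tail bound where applicable.
#'
#' @param sol A `capform_fields` object ([analytic_fields()] or
#'   [solve_nonlinear()]).
#' @param stem Output path without extension.
#' @return Invisibly, the two file paths.
#' @export
export_fields <- function(sol, stem) {
  tab <- as.data.frame(sol)
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  write_fields_csv(tab, csv)
  meta <- list(provenance = sol$provenance,
               n_nodes = length(sol$y),
               times = sol$times,
               params = if (!is.null(sol$params_snapshot))
                 unclass(sol$params_snapshot),
               N = sol$N, tail_bound = sol$tail_bound)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))], json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = json))
}

#' @export
as.data.frame.capform_fields <- function(x, ...) {
  nt <- length(x$times)
  do.call(rbind, lapply(seq_len(nt), function(i) {
    data.frame(y = x$y, t = x$times[i], v = x$v[i, ], c = x$c[i, ],
               f = x$f[i, ], eta = x$eta[i, ])
  }))
}
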