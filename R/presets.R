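#' Named parameter presets
#'
#' Ready-made configurations so that every demonstration and test runs
#' without external data. `"example2013"` is the worked example:
#' `epsilon = 0.05`, `lambda = 20`, `mu = 5`, `beta = 10`, `K = 0.1`,
#' `D_eta = 0.25` with the quartic bump profile (`m = 2`, `A = 30`).
#' `"rest"` is the same with `epsilon = 0` (nothing moves). Variants
#' `"example2013-m3"` and `"example2013-m1"` swap in steeper / shallower
#' bump profiles for exploring bimodality onset.
#'
#' The full transition-constant set behind each preset is built with
#' [compatible_params()], so the nonlinear solver's derived `K` matches the
#' preset's `K` exactly.
#'
#' @param name Preset name.
#' @return A `capform_preset`: list with `name`, `config`
#'   (a [perturbation_config()]), `params` (a [model_params()]), `notes`.
#' @examples
#' pr <- load_preset("example2013")
#' pr$config$K        # 0.1
#' pr$params$D_eta    # 0.25
#' @export
load_preset <- function(name) {
  builders <- list(
    "example2013" = function() preset_example(0.05, 2L),
    "rest" = function() preset_example(0, 2L),
    "example2013-m3" = function() preset_example(0.05, 3L),
    "example2013-m1" = function() preset_example(0.05, 1L)
  )
  if (!name %in% names(builders))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(builders), collapse = ", ")), call. = FALSE)
  builders[[name]]()
}

preset_example <- function(epsilon, m) {
  params <- compatible_params(K = 0.1, lambda = 20, mu = 5, beta = 10,
                              D_eta = 0.25)
  theta <- if (m == 1L) suppressWarnings(bump_profile(1L)) else bump_profile(m)
  structure(list(
    name = if (epsilon == 0) "rest" else sprintf("example2013-m%d", m),
    config = perturbation_config(epsilon, theta, params = params),
    params = params,
    notes = paste("worked example: epsilon=0.05, lambda=20, mu=5, beta=10,",
                  "K=0.1, D_eta=0.25; gamma1 rescaled so the full parameter",
                  "set reproduces K")),
    class = "capform_preset")
}

#' @export
print.capform_preset <- function(x, ...) {
  cat(sprintf("<capform_preset '%s'>  epsilon=%g K=%g profile=%s\n",
              x$name, x$config$epsilon, x$config$K, x$config$theta$label))
  invisible(x)
}

#' Reference field tables
#'
#' Tabulates the analytic fields of a preset on a grid and time list as a
#' long-format data.frame `(y, t, v, c, f, eta)`, optionally written to
#' CSV. Everything in this package is deterministic arithmetic, so
#' regeneration is reproducible bit-for-bit on the same platform.
#'
#' @param preset A [load_preset()] object.
#' @param grid A [make_grid()] object or node count (>= 21); smaller tables
#'   can use an integer `n_nodes` instead.
#' @param times Output times.
#' @param n_nodes Alternative to `grid`: number of equispaced evaluation
#'   points (no minimum; the table is an evaluation, not a solver grid).
#' @param file Optional CSV path; written with 12 significant digits.
#' @param N Series truncation order.
#' @return The data.frame, invisibly if `file` is given.
#' @export
reference_tables <- function(preset, grid = NULL, times = c(0, 0.05, 0.1),
                             n_nodes = 11, file = NULL, N = 200) {
  y <- if (!is.null(grid)) {
    if (is.numeric(grid)) make_grid(grid)$y else grid$y
  } else seq(0, 1, length.out = n_nodes)
  spectrum <- fourier_spectrum(preset$config$theta, preset$config$K, N)
  rows <- lapply(times, function(t) {
    fl <- assemble_fields(y, t, preset$config, preset$params,
                          spectrum = spectrum)
    data.frame(y = y, t = t, v = fl$v, c = fl$c, f = fl$f, eta = fl$eta)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(file)) {
    write_fields_csv(tab, file)
    return(invisible(tab))
  }
  tab
}
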