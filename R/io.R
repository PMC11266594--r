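CONFIG_KEYS <- list(
  top = c("biofilm", "gas", "regime", "dimensional", "enn"),
  biofilm = c("phi", "beta", "phi1", "beta1", "alpha"),
  gas = c("A", "A1", "gamma"),
  dimensional = c("D_em", "D_ep", "X", "Y_m", "Y_p", "mu_max_m", "mu_max_p",
                  "K_m", "K_p", "K_i", "delta", "m_m", "m_p", "U_g", "A_s",
                  "H", "C_mi", "C_pi"),
  enn = c("n_hidden", "max_iterations", "mu0", "mu_up", "mu_down", "mu_max",
          "grad_tol", "val_patience", "split", "seed"))

#' Load and validate a model configuration file
#'
#' Reads a YAML or JSON configuration with sections `biofilm`
#' (`phi, beta, phi1, beta1, alpha`), `gas` (`A, A1, gamma`), `regime`,
#' an optional `enn` block of [enn_config()] overrides, and an optional
#' `dimensional` block of physical parameters which is converted to the
#' dimensionless groups on load (overriding any explicit `biofilm`/`gas`
#' values).  Unknown keys anywhere are an error; omitted values take the
#' documented defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `biofilm` ([biofilm_params()]), `gas`
#'   ([gas_params()]), `regime`, `enn` ([enn_config()]) and `dimensional`
#'   (the raw block or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("config must be a mapping")
  check_keys(raw, CONFIG_KEYS$top, "top level")
  for (sec in c("biofilm", "gas", "dimensional", "enn")) {
    if (!is.null(raw[[sec]])) check_keys(raw[[sec]], CONFIG_KEYS[[sec]], sec)
  }

  regime <- match_regime(raw$regime %||% "michaelis_menten")

  dimensional <- NULL
  if (!is.null(raw$dimensional)) {
    dimensional <- do.call(dimensional_params, raw$dimensional)
    biofilm <- nondimensionalize_biofilm(dimensional,
                                         alpha = raw$biofilm$alpha %||% 1)
    gas <- nondimensionalize_gas(dimensional)
  } else {
    bf <- raw$biofilm %||% list()
    biofilm <- biofilm_params(phi = bf$phi %||% 0, beta = bf$beta %||% 0,
                              phi1 = bf$phi1 %||% 0, beta1 = bf$beta1 %||% 0,
                              alpha = bf$alpha %||% 1)
    gp <- raw$gas %||% list()
    gas <- gas_params(A = gp$A %||% 0, A1 = gp$A1 %||% 0,
                      gamma = gp$gamma %||% 0)
  }
  enn <- do.call(enn_config, raw$enn %||% list())
  list(biofilm = biofilm, gas = gas, regime = regime, enn = enn,
       dimensional = dimensional)
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key%s in %s: %s",
                 if (length(unknown) > 1) "s" else "", where,
                 paste(unknown, collapse = ", ")))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write solved profiles as a fixed-precision CSV table
#'
#' Writes one or more profiles sharing a grid as a CSV with the grid in
#' the first column and one 6-decimal fixed-point column per profile --
#' the layout used for printed solution tables.  Reading the file back
#' returns values identical to the written (rounded) ones.
#'
#' @param profiles A single profile or named list of profiles
#'   (`biofilm_profile` or `column_profile`) sharing an identical grid.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  if (inherits(profiles, c("biofilm_profile", "column_profile")))
    profiles <- list(profiles)
  cols <- lapply(profiles, profile_columns)
  grid <- cols[[1]]$grid
  for (p in cols[-1]) {
    if (length(p$grid) != length(grid) || max(abs(p$grid - grid)) > 1e-12)
      stop("all profiles must share the same grid")
  }
  values <- do.call(cbind, lapply(cols, `[[`, "values"))
  header <- unlist(lapply(seq_along(cols), function(i) {
    nm <- names(profiles)[i] %||% ""
    if (!nzchar(nm)) nm <- cols[[i]]$default_name
    paste0(nm, if (ncol(cols[[i]]$values) > 1)
      paste0("_", colnames(cols[[i]]$values)) else "")
  }))
  df <- data.frame(format_fixed(grid),
                   apply(values, 2, format_fixed),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(cols[[1]]$grid_name, header)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

profile_columns <- function(p) {
  if (inherits(p, "biofilm_profile")) {
    list(grid = p$grid, grid_name = "X",
         values = matrix(p$s_values, dimnames = list(NULL, "S")),
         default_name = paste0("S_", p$species))
  } else if (inherits(p, "column_profile")) {
    list(grid = p$h_grid, grid_name = "h",
         values = cbind(C_m = p$c_m_values, C_p = p$c_p_values,
                        alpha = p$alpha_values),
         default_name = "column")
  } else {
    stop("unsupported profile object")
  }
}

format_fixed <- function(x) sprintf("%.6f", x)

#' Read a profile table written by [write_profile_table()]
#'
#' @param path CSV path.
#' @return Data frame of numeric columns.
#' @export
read_profile_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Reference solution fixtures for the printed parameter scenarios
#'
#' Returns the benchmark scenarios used throughout: the five biofilm
#' parameter sets with published Runge-Kutta reference values at
#' `X* = 0, 0.2, ..., 1`, plus the four multi-run statistics scenarios
#' (parameters only).  These anchor the regression tests of the solver.
#'
#' @return Named list of `scenario_fixture` objects, each with `name`,
#'   `params` ([biofilm_params()]), `species`, `regime` and `expected`
#'   (data frame `x`, `s`, `source`; `NULL` for the statistics-only
#'   scenarios).
#' @export
fixture_registry <- function() {
  xs <- seq(0, 1, by = 0.2)
  fx <- function(name, params, species, values = NULL) {
    expected <- if (!is.null(values))
      data.frame(x = xs, s = values, source = "rk4")
    structure(list(name = name, params = params, species = species,
                   regime = "michaelis_menten", expected = expected),
              class = "scenario_fixture")
  }
  list(
    methanol_phi10_beta10 = fx(
      "methanol phi=10 beta=10", biofilm_params(phi = 10, beta = 10),
      "methanol",
      c(1, 0.843313, 0.722383, 0.636594, 0.585389, 0.568368)),
    methanol_phi10_beta15 = fx(
      "methanol phi=10 beta=15", biofilm_params(phi = 10, beta = 15),
      "methanol",
      c(1, 0.889549, 0.803907, 0.742891, 0.706351, 0.694182)),
    methanol_phi10_beta300 = fx(
      "methanol phi=10 beta=300", biofilm_params(phi = 10, beta = 300),
      "methanol",
      c(1, 0.994020, 0.989369, 0.986047, 0.984054, 0.983389)),
    pinene_phi1_0.1_beta1_10 = fx(
      "pinene alpha=1 phi1=0.1 beta1=10",
      biofilm_params(phi1 = 0.1, beta1 = 10, alpha = 1), "pinene",
      c(1, 0.998364, 0.997092, 0.996183, 0.995638, 0.995456)),
    pinene_phi1_4_beta1_10 = fx(
      "pinene alpha=1 phi1=4 beta1=10",
      biofilm_params(phi1 = 4, beta1 = 10, alpha = 1), "pinene",
      c(1, 0.935439, 0.885333, 0.849605, 0.828194, 0.821062)),
    stats_phi10_beta10 = fx(
      "stats phi=beta=10", biofilm_params(phi = 10, beta = 10), "methanol"),
    stats_phi10_beta300 = fx(
      "stats phi=10 beta=300", biofilm_params(phi = 10, beta = 300),
      "methanol"),
    stats_pinene_all1 = fx(
      "stats phi1=beta1=alpha=1",
      biofilm_params(phi1 = 1, beta1 = 1, alpha = 1), "pinene"),
    stats_pinene_beta1_100 = fx(
      "stats phi1=alpha=1 beta1=100",
      biofilm_params(phi1 = 1, beta1 = 100, alpha = 1), "pinene"))
}

#' Run manifest for reproducible outputs
#'
#' Records the configuration, seed, package version, timestamp and output
#' paths of a run; serialized as JSON next to the results so any run can
#' be reconstructed.
#'
#' @param config Configuration list (as from [load_config()]) or any
#'   serializable list.
#' @param seed Integer seed(s) used.
#' @param outputs Character vector of output file paths.
#' @param path Optional path to write the manifest JSON.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(config, seed, outputs, path = NULL) {
  manifest <- list(
    package = "biofiltervoc",
    version = as.character(utils::packageVersion("biofiltervoc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = manifest_config(config),
    outputs = as.character(outputs))
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(manifest))
  }
  manifest
}

manifest_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}
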