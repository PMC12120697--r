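#' Design grid of print parameters
#'
#' The factorial design space used throughout the package: two bioink
#' viscosities, three nozzle inner diameters, three dispensing times, two
#' printing pressures and two cell concentrations (stored as cells/mL;
#' 2.8e6 cells in 3 mL of bioink is 9.333e5 cells/mL).
#'
#' @return A named list of the level vectors.
#' @export
design_levels <- function() {
  list(
    viscosity_mPa_s = c(10.03, 24.66),
    nozzle_id_mm = c(0.337, 0.26, 0.21),
    printing_time_s = c(0.05, 0.1, 0.15),
    pressure_psi = c(1.5, 2),
    cell_conc_per_mL = c(2.8e6 / 3, 5.6e6 / 3)
  )
}

#' Names of the five predictor columns
#' @return Character vector of feature column names, in canonical order.
#' @export
feature_names <- function() {
  c("viscosity_mPa_s", "nozzle_id_mm", "printing_time_s",
    "pressure_psi", "cell_conc_per_mL")
}

#' Configuration for the synthetic parameter-to-volume generator
#'
#' Defines a deterministic power-law response surface over the print
#' parameters plus a multiplicative noise level. Two presets are provided:
#'
#' * `"paper-ranked"` (default): exponents chosen so the response span over
#'   the design grid is ordered dispensing time > nozzle diameter > pressure >
#'   viscosity > cell concentration, i.e. the qualitative importance ranking
#'   observed on real dispensing hardware.
#' * `"poiseuille"`: nozzle exponent 4, the scaling a naive Hagen-Poiseuille
#'   throughput argument would predict; useful as a physically motivated
#'   stress test in which nozzle diameter dominates.
#'
#' The anchor parameters default to the midpoints of the design grid
#' (geometric midpoints for the all-positive viscosity and pressure) and the
#' anchor volume to 6.54 uL, a realistic medium droplet for this design
#' space, so the noiseless surface spans roughly 1.8-19.3 uL over the grid.
#'
#' @param preset `"paper-ranked"` or `"poiseuille"`.
#' @param a_t,a_d,a_P,a_mu,a_c Exponents/sensitivities for time, nozzle
#'   diameter, pressure, viscosity and cell concentration. Defaults depend on
#'   the preset.
#' @param anchor_volume_uL Volume at the anchor parameters, uL.
#' @param anchor_params Named list of the five reference parameter values.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian volume
#'   noise applied by [generate_records()].
#' @param seed Default seed used by [generate_records()] when none is given.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(preset = c("paper-ranked", "poiseuille"),
                             a_t = 1, a_d = NULL, a_P = 1, a_mu = 0.3,
                             a_c = 0.02,
                             anchor_volume_uL = 6.54,
                             anchor_params = NULL,
                             noise_cv = 0.02,
                             seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(a_d)) a_d <- if (preset == "poiseuille") 4 else 1.5
  if (is.null(anchor_params)) {
    lv <- design_levels()
    anchor_params <- list(
      viscosity_mPa_s = sqrt(prod(lv$viscosity_mPa_s)),
      nozzle_id_mm = 0.26,
      printing_time_s = 0.1,
      pressure_psi = sqrt(prod(lv$pressure_psi)),
      cell_conc_per_mL = mean(lv$cell_conc_per_mL)
    )
  }
  stopifnot(
    all(vapply(list(a_t, a_d, a_P, a_mu, a_c), is.finite, logical(1))),
    is.finite(anchor_volume_uL), anchor_volume_uL > 0,
    is.finite(noise_cv), noise_cv >= 0,
    setequal(names(anchor_params), feature_names()) ||
      setequal(names(anchor_params),
               c("viscosity_mPa_s", "nozzle_id_mm", "printing_time_s",
                 "pressure_psi", "cell_conc_per_mL"))
  )
  structure(
    list(preset = preset, a_t = a_t, a_d = a_d, a_P = a_P, a_mu = a_mu,
         a_c = a_c, anchor_volume_uL = anchor_volume_uL,
         anchor_params = anchor_params, noise_cv = noise_cv,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    paste0("<generator_config> preset = %s\n",
           "  exponents: time %g, nozzle %g, pressure %g, viscosity -%g, cells %g\n",
           "  anchor %g uL at (mu %.4g, d %.3g, t %.3g, P %.4g, c %.4g)\n",
           "  noise_cv %g, seed %d\n"),
    x$preset, x$a_t, x$a_d, x$a_P, x$a_mu, x$a_c, x$anchor_volume_uL,
    x$anchor_params$viscosity_mPa_s, x$anchor_params$nozzle_id_mm,
    x$anchor_params$printing_time_s, x$anchor_params$pressure_psi,
    x$anchor_params$cell_conc_per_mL, x$noise_cv, x$seed))
  invisible(x)
}

#' Noiseless droplet volume from print parameters
#'
#' Evaluates the deterministic response surface of a [generator_config()] on
#' a data frame of print parameters:
#'
#' \deqn{V = V_0 (P/P_0)^{a_P} (t/t_0)^{a_t} (d/d_0)^{a_d}
#'       (\mu/\mu_0)^{-a_\mu} (1 + a_c (c - c_0)/c_0)}
#'
#' @param params Data frame with the five columns of [feature_names()].
#' @param config A [generator_config()].
#' @return Numeric vector of noiseless volumes, uL.
#' @export
volume_model <- function(params, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"), is.data.frame(params))
  missing_cols <- setdiff(feature_names(), names(params))
  if (length(missing_cols)) {
    stop_dropsizer(paste0("`params` is missing column(s): ",
                          paste(missing_cols, collapse = ", ")),
                   class = "dropsizer_error_schema")
  }
  num_ok <- vapply(
    params[feature_names()],
    function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0),
    logical(1)
  )
  if (!all(num_ok)) {
    stop_dropsizer("All print parameters must be positive and finite.",
                   class = "dropsizer_error_domain")
  }
  a0 <- config$anchor_params
  config$anchor_volume_uL *
    (params$pressure_psi / a0$pressure_psi)^config$a_P *
    (params$printing_time_s / a0$printing_time_s)^config$a_t *
    (params$nozzle_id_mm / a0$nozzle_id_mm)^config$a_d *
    (params$viscosity_mPa_s / a0$viscosity_mPa_s)^(-config$a_mu) *
    (1 + config$a_c *
       (params$cell_conc_per_mL - a0$cell_conc_per_mL) / a0$cell_conc_per_mL)
}

#' Simulate a parameter-to-volume dataset over the design grid
#'
#' Samples `n` print records uniformly from the factorial design grid, with
#' the two viscosity levels exactly balanced (`floor(n/2)` / `ceiling(n/2)`),
#' and attaches a measured volume: the noiseless [volume_model()] response
#' times `(1 + eps)` with `eps ~ N(0, noise_cv)`, truncated to stay positive.
#'
#' @param n Number of records (>= 1).
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to the config's seed.
#' @return A tibble with the five predictor columns plus `volume_uL`.
#' @examples
#' records <- generate_records(100, generator_config(seed = 7))
#' @export
generate_records <- function(n, config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop_dropsizer("`n` must be a positive count.", class = "dropsizer_error_config")
  }
  n <- as.integer(n)
  lv <- design_levels()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  n_lo <- n %/% 2L
  visc <- sample(c(rep(lv$viscosity_mPa_s[1], n_lo),
                   rep(lv$viscosity_mPa_s[2], n - n_lo)))
  params <- tibble::tibble(
    viscosity_mPa_s = visc,
    nozzle_id_mm = sample(lv$nozzle_id_mm, n, replace = TRUE),
    printing_time_s = sample(lv$printing_time_s, n, replace = TRUE),
    pressure_psi = sample(lv$pressure_psi, n, replace = TRUE),
    cell_conc_per_mL = sample(lv$cell_conc_per_mL, n, replace = TRUE)
  )
  v0 <- volume_model(params, config)
  eps <- stats::rnorm(n, mean = 0, sd = config$noise_cv)
  v <- v0 * (1 + eps)
  v <- pmax(v, .Machine$double.eps * v0) # volumes stay strictly positive
  dplyr::mutate(params, volume_uL = v)
}
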