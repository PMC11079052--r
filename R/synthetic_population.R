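#' Parameters for a synthetic cell population under a buffering regime
#'
#' Describes how a population of transfected cells responds to variation in
#' total expression `E` of a focus-forming protein. Two regimes are modeled:
#'
#' * `concentration_buffering` (the phase-separation expectation): the
#'   concentration inside foci is pinned at the saturation value `c_sat`
#'   regardless of `E`, foci grow in area proportionally to `E`, and the
#'   nucleoplasm concentration rises only weakly
#'   (`(E / E_min)^nucleoplasm_response`).
#' * `size_buffering`: foci area and count stay fixed up to noise while the
#'   concentrations inside foci and in the nucleoplasm both scale linearly
#'   with `E`, so their ratio is stable.
#'
#' Expression is drawn log-uniform over `expression_log10_range` (broad,
#' decade-spanning distributions are typical of transient transfection).
#' Multiplicative lognormal noise with coefficient of variation `noise_cv`
#' (unit mean) is applied to every measured quantity; `noise_cv = 0` gives
#' the exact noise-free relations.
#'
#' @param regime `"concentration_buffering"` or `"size_buffering"`.
#' @param n_cells number of cells (>= 3).
#' @param c_sat fixed focus concentration under concentration buffering (a.u.).
#' @param nucleoplasm_sat baseline nucleoplasm concentration (a.u.).
#' @param expression_log10_range length-2 numeric, log10 range of `E`.
#' @param foci_count_fixed baseline foci count per cell.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param area_scale_um2 foci area (micrometers squared) of a cell at
#'   `E = c_sat` under concentration buffering, and the fixed mean foci area
#'   under size buffering.
#' @param nucleoplasm_response exponent of the weak nucleoplasm rise under
#'   concentration buffering (0 pins the nucleoplasm exactly).
#' @return an object of class `population_params`.
#' @seealso [simulate_population()], [run_buffering_test()]
#' @export
population_params <- function(regime = c("concentration_buffering", "size_buffering"),
                              n_cells = 100L,
                              c_sat = 200,
                              nucleoplasm_sat = 50,
                              expression_log10_range = c(0, 2),
                              foci_count_fixed = 12L,
                              noise_cv = 0.1,
                              seed = 1L,
                              area_scale_um2 = 15,
                              nucleoplasm_response = 0.2) {
  regime <- match.arg(regime)
  stop_if_not(is_count(n_cells, 3), "n_cells must be an integer >= 3")
  stop_if_not(is_number(c_sat) && c_sat > 0, "c_sat must be positive")
  stop_if_not(is_number(nucleoplasm_sat) && nucleoplasm_sat > 0,
              "nucleoplasm_sat must be positive")
  stop_if_not(length(expression_log10_range) == 2L &&
                diff(expression_log10_range) > 0,
              "expression_log10_range must be a non-degenerate increasing pair")
  stop_if_not(is_count(foci_count_fixed, 1), "foci_count_fixed must be >= 1")
  stop_if_not(is_number(noise_cv, 0), "noise_cv must be >= 0")
  stop_if_not(is_number(nucleoplasm_response, 0),
              "nucleoplasm_response must be >= 0")
  structure(list(regime = regime, n_cells = as.integer(n_cells), c_sat = c_sat,
                 nucleoplasm_sat = nucleoplasm_sat,
                 expression_log10_range = as.numeric(expression_log10_range),
                 foci_count_fixed = as.integer(foci_count_fixed),
                 noise_cv = noise_cv, seed = as.integer(seed),
                 area_scale_um2 = area_scale_um2,
                 nucleoplasm_response = nucleoplasm_response),
            class = "population_params")
}

#' Simulate a per-cell measurement table under a buffering regime
#'
#' @param params a `population_params` object.
#' @return a data frame of class `cell_population` with one row per cell and
#'   columns `cell_id`, `total_expression`, `foci_concentration`,
#'   `foci_area_um2`, `foci_count`, `nucleoplasm_concentration`,
#'   `ratio_foci_nucleoplasm`. The generating parameters are attached as
#'   attribute `"params"`.
#' @examples
#' pop <- simulate_population(population_params("size_buffering", seed = 3))
#' head(pop)
#' @export
simulate_population <- function(params) {
  stop_if_not(inherits(params, "population_params"),
              "params must be population_params()")
  p <- params
  withr::with_seed(p$seed, {
    lo <- p$expression_log10_range[1]
    e <- 10^runif(p$n_cells, lo, p$expression_log10_range[2])
    e_min <- 10^lo
    noise <- function() {
      if (p$noise_cv == 0) rep(1, p$n_cells)
      else {
        s2 <- log(1 + p$noise_cv^2)
        rlnorm(p$n_cells, meanlog = -s2 / 2, sdlog = sqrt(s2))
      }
    }
    if (p$regime == "concentration_buffering") {
      foci_conc <- p$c_sat * noise()
      nucleoplasm <- p$nucleoplasm_sat * (e / e_min)^p$nucleoplasm_response * noise()
      foci_area <- p$area_scale_um2 * (e / p$c_sat) * noise()
      foci_count <- pmax(1L, as.integer(round(p$foci_count_fixed * noise())))
    } else {
      foci_conc <- p$c_sat * (e / e_min) * noise()
      nucleoplasm <- p$nucleoplasm_sat * (e / e_min) * noise()
      foci_area <- p$area_scale_um2 * noise()
      foci_count <- pmax(1L, as.integer(round(p$foci_count_fixed * noise())))
    }
    out <- data.frame(
      cell_id = seq_len(p$n_cells),
      total_expression = e,
      foci_concentration = foci_conc,
      foci_area_um2 = foci_area,
      foci_count = foci_count,
      nucleoplasm_concentration = nucleoplasm,
      ratio_foci_nucleoplasm = foci_conc / nucleoplasm
    )
    attr(out, "params") <- p
    class(out) <- c("cell_population", "data.frame")
    out
  })
}

#' Write / read a per-cell population table as CSV
#'
#' @param population a `cell_population` data frame.
#' @param path file path.
#' @return `write_population()` returns the path invisibly;
#'   `read_population()` returns the data frame.
#' @export
write_population <- function(population, path) {
  write.csv(as.data.frame(population), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  out <- read.csv(path)
  class(out) <- c("cell_population", "data.frame")
  out
}
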