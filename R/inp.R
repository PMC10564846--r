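#' Ice-nucleating-particle spectrum from a frozen-fraction assay
#'
#' Droplet-freezing assays immerse filter punches in wells of ultrapure
#' water, cool at a constant rate, and record the cumulative number of
#' frozen wells on a 0.1 K grid. Under Poisson statistics the cumulative
#' INP concentration per mL of well suspension at temperature T is
#' \deqn{c_{well}(T) = -\ln(1 - f(T)) / V_{well}}
#' with f the frozen fraction and V the well volume. Scaling to the source
#' water uses the fraction of the filter area carried by one punch:
#' \deqn{c_{src}(T) = -\ln(1 - f(T)) / (V_{filtered} \cdot A_{punch}/A_{filter})}
#' with A = pi (d/2)^2. Wells all frozen (f = 1) make the log diverge; such
#' rows are flagged `censored` and reported as a lower bound using a
#' half-count continuity correction, (frozen - 0.5) / total.
#'
#' @param assay A data frame with columns `temp_c` (degrees Celsius,
#'   decreasing grid) and `frozen` (cumulative frozen wells), one assay.
#' @param total_wells Number of wells (default 24, one quarter of a 96-well
#'   tray).
#' @param v_well_ul Well suspension volume in microlitres (default 50).
#' @param punch_d_mm Punch diameter in mm (default 1).
#' @param filter_d_mm Filter membrane diameter in mm (default 47).
#' @param v_filtered_ml Volume of source water passed through the filter, in
#'   mL; `NA` suppresses the per-source-water column.
#' @return A tibble of class `inp_spectrum`: `temp_c`, `frozen`,
#'   `f_frozen`, `censored`, `c_inp_per_ml_suspension`, and (when the
#'   filtered volume is known) `c_inp_per_ml_source`.
#' @export
#' @examples
#' assay <- data.frame(temp_c = c(-5, -6, -7), frozen = c(0, 12, 24))
#' inp_spectrum(assay, total_wells = 24, v_filtered_ml = 500)
inp_spectrum <- function(assay, total_wells = 24, v_well_ul = 50,
                         punch_d_mm = 1, filter_d_mm = 47,
                         v_filtered_ml = NA_real_) {
  assert_columns(assay, c("temp_c", "frozen"), "freezing assay")
  stopifnot(total_wells >= 1, v_well_ul > 0, punch_d_mm > 0, filter_d_mm > 0)
  assay <- as_tibble(assay) %>% arrange(dplyr::desc(.data$temp_c))
  if (any(assay$frozen < 0) || any(assay$frozen > total_wells)) {
    abort("Cumulative frozen counts must lie in [0, total_wells].")
  }
  if (is.unsorted(assay$frozen)) {
    abort("Cumulative frozen counts must be nondecreasing with cooling.")
  }
  f_raw <- assay$frozen / total_wells
  censored <- f_raw >= 1
  f_eff <- ifelse(censored, (assay$frozen - 0.5) / total_wells, f_raw)
  nlog <- -log(1 - f_eff)
  v_well_ml <- v_well_ul / 1000
  area_frac <- (punch_d_mm / filter_d_mm)^2   # pi r^2 ratio; pi cancels
  out <- tibble(
    temp_c = assay$temp_c,
    frozen = assay$frozen,
    f_frozen = f_raw,
    censored = censored,
    c_inp_per_ml_suspension = nlog / v_well_ml
  )
  if (!is.na(v_filtered_ml)) {
    out$c_inp_per_ml_source <- nlog / (v_filtered_ml * area_frac)
  }
  class(out) <- c("inp_spectrum", class(out))
  out
}
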