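#' Reference ESI-source response-surface model
#'
#' The fitted second-order model for summed flavonoid peak area from the
#' Box-Behnken optimization of the electrospray source of this assay, in
#' coded units with factor order Nebulizer (psi), sheath gas temperature
#' (°C), nozzle voltage (V):
#' \deqn{Y = 2398 - 328.12 x_1 + 121.5 x_2 + 325.37 x_3 + 35.87 x_1^2
#'   - 45 x_1 x_2 - 52.75 x_1 x_3 - 23.38 x_2^2 + 10.5 x_2 x_3
#'   - 74.63 x_3^2.}
#' Its unconstrained stationary point lies outside the explored cube and
#' is a saddle, so the operating optimum is the cube-constrained maximum
#' (see [constrained_optimum]): nebulizer 40 psi, SGT 400 °C, nozzle
#' voltage 1500 V.
#'
#' @return An `rsm_fit` built by [quadratic_model], carrying the
#'   [esi_factors] `"bbd"` factor set for decoding.
#' @export
esi_surface_model <- function() {
  quadratic_model(
    b0 = 2398,
    linear = c(-328.12, 121.5, 325.37),
    quadratic = c(35.87, -23.38, -74.63),
    interaction = c(-45, -52.75, 10.5),   # x1:x2, x1:x3, x2:x3
    factors = esi_factors("bbd"))
}
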