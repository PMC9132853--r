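#' Tissue and model parameters
#'
#' Electrical material constants of the homogenised muscle model and the
#' surrounding inactive tissue. Units follow the package-wide convention:
#' lengths in cm, time in ms, potentials in mV, conductivities in mS/cm,
#' membrane capacitance in uF/cm^2, current densities in uA/cm^2.
#'
#' @param sigma_i_l longitudinal intracellular conductivity (mS/cm). The
#'   default 8.93 is a classical measurement on frog sartorius.
#' @param sigma_i_t transversal intracellular conductivity (mS/cm). The
#'   homogenised intracellular domains conduct only along the fibre
#'   direction, hence 0.
#' @param sigma_e_l longitudinal extracellular conductivity (mS/cm).
#' @param sigma_e_t transversal extracellular conductivity (mS/cm).
#' @param sigma_b conductivity of the inactive body region (fat), mS/cm,
#'   isotropic.
#' @param C_m membrane capacitance per unit area (uF/cm^2).
#' @param A_m fibre surface-to-volume ratio (1/cm).
#' @param mu_0 vacuum permeability in SI units (T m/A). Biological tissue is
#'   assumed non-magnetic, so the same permeability holds everywhere.
#' @return A named list of class `tissue_parameters`.
#' @export
#' @examples
#' p <- tissue_parameters()
#' p$sigma_i_l
tissue_parameters <- function(sigma_i_l = 8.93,
                              sigma_i_t = 0.0,
                              sigma_e_l = 6.7,
                              sigma_e_t = 3.35,
                              sigma_b = 0.4,
                              C_m = 1,
                              A_m = 500,
                              mu_0 = 4e-7 * pi) {
  stopifnot(sigma_i_l >= 0, sigma_i_t >= 0, sigma_e_l >= 0, sigma_e_t >= 0,
            sigma_b >= 0, C_m > 0, A_m > 0, mu_0 > 0)
  structure(list(sigma_i_l = sigma_i_l, sigma_i_t = sigma_i_t,
                 sigma_e_l = sigma_e_l, sigma_e_t = sigma_e_t,
                 sigma_b = sigma_b, C_m = C_m, A_m = A_m, mu_0 = mu_0),
            class = "tissue_parameters")
}

#' Hodgkin-Huxley membrane parameters
#'
#' The classic squid-axon parameter set in the physiological-voltage
#' convention (resting potential near -75 mV), matching the standard CellML
#' encoding of the 1952 model. Conductances in mS/cm^2, reversal potentials
#' in mV.
#'
#' @param g_Na,g_K,g_L maximal sodium, potassium and leak conductances
#'   (mS/cm^2).
#' @param E_Na,E_K,E_L reversal potentials (mV). `E_L` is tuned so the
#'   resting state is an equilibrium close to -75 mV.
#' @param C_m membrane capacitance (uF/cm^2).
#' @return A named list of class `hh_parameters`.
#' @export
hh_parameters <- function(g_Na = 120, g_K = 36, g_L = 0.3,
                          E_Na = 40, E_K = -87, E_L = -64.387,
                          C_m = 1) {
  structure(list(g_Na = g_Na, g_K = g_K, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L, C_m = C_m),
            class = "hh_parameters")
}
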