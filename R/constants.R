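# Physical constants (CODATA-2018 rounded; MeV / cm / g unit system).

#' @keywords internal
.fs <- list(
  mec2      = 0.51099895,      # electron rest energy, MeV
  re        = 2.8179403262e-13,  # classical electron radius, cm
  NA_       = 6.02214076e23,   # Avogadro, 1/mol
  alpha     = 7.2973525693e-3, # fine-structure constant
  euler     = 0.57721566490153286,
  # 2 pi re^2 mec2 NA: prefactor of the Bethe collision stopping power,
  # MeV cm^2 / g per unit (Z/A)
  bethe_k   = 2 * pi * (2.8179403262e-13)^2 * 0.51099895 * 6.02214076e23,
  # 4 pi NA re^2 mec2^2: prefactor of the Moliere characteristic angle
  # chi_c^2, MeV^2 cm^2 / g per unit (Z(Z+1)/A)
  chic_k    = 4 * pi * 6.02214076e23 * (2.8179403262e-13)^2 * 0.51099895^2,
  # alpha re^2 NA: prefactor of the bremsstrahlung stopping power,
  # cm^2 / mol
  brems_k   = 7.2973525693e-3 * (2.8179403262e-13)^2 * 6.02214076e23,
  # plasma-energy prefactor: hbar omega_p = 28.8159 sqrt(rho Z/A) eV
  plasma_k  = 28.8159,
  # Moliere e^(2 C_E - 1) entering Omega_0 = chi_c^2 / (1.167 chi_a^2)
  moliere_e2c = 1.167,
  # reduced-Gaussian correction: theta^2 -> theta^2 (1 - 1.330/B)
  rg_const  = 1.330
)

# kinematic helpers: E is the electron kinetic energy in MeV
.kin <- function(E) {
  tau <- E / .fs$mec2
  gamma <- tau + 1
  beta2 <- 1 - 1 / gamma^2
  pc2 <- E * (E + 2 * .fs$mec2)          # (pc)^2, MeV^2
  list(tau = tau, gamma = gamma, beta2 = beta2, pc2 = pc2,
       pbc = pc2 / (E + .fs$mec2))        # p v = p beta c, MeV
}
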